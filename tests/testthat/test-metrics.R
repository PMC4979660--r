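test_that("every metric matches its brute-force oracle on random small pairs", {
  set.seed(421)
  names_all <- metric_registry(include_nestedness = FALSE)$name
  oracle_names <- setdiff(names_all, c("baselga_bc_nest", "baselga_r_nest",
                                       "podani_bc_nest", "podani_r_nest"))
  for (rep in 1:100) {
    pr <- random_small_pair()
    pair <- assemblage_pair(pr$x, pr$y)
    mine <- beta_pair(pair, oracle_names, ness_m = 5)
    for (nm in oracle_names) {
      ref <- oracle_beta(nm, pr$x, pr$y, ness_m = 5)
      if (is.na(ref)) {
        expect_true(is.na(mine[[nm]]), info = nm)
      } else {
        expect_equal(unname(mine[[nm]]), ref, tolerance = 1e-12, info = nm)
      }
    }
  }
})

test_that("metrics agree with the vegan reference implementations", {
  skip_if_not_installed("vegan")
  set.seed(77)
  map <- c(bray_curtis = "bray", kulczynski = "kulczynski", gower = "gower",
           alt_gower = "altGower", canberra = "canberra",
           morisita = "morisita", morisita_horn = "horn",
           binomial = "binomial", cyd = "cao", chao_jaccard = "chao",
           ruzicka = "jaccard", manhattan = "manhattan",
           euclidean = "euclidean")
  for (rep in 1:40) {
    pr <- random_small_pair()
    m <- rbind(pr$x, pr$y)
    for (nm in names(map)) {
      ref <- as.numeric(vegan::vegdist(m, method = map[[nm]]))
      expect_equal(beta(nm, assemblage_pair(pr$x, pr$y)), ref,
                   tolerance = 1e-10, info = nm)
    }
  }
})

test_that("metrics are symmetric and zero on identical pairs", {
  set.seed(99)
  names_all <- metric_registry(include_nestedness = TRUE)$name
  for (rep in 1:500) {
    pr <- random_small_pair()
    v1 <- beta_pair(assemblage_pair(pr$x, pr$y), names_all, ness_m = 5)
    v2 <- beta_pair(assemblage_pair(pr$y, pr$x), names_all, ness_m = 5)
    na_match <- is.na(v1) == is.na(v2)
    expect_true(all(na_match))
    ok <- !is.na(v1)
    expect_true(all(abs(v1[ok] - v2[ok]) < 1e-12))
    expect_true(all(v1[ok] > -1e-12)) # minimum of zero
  }
  for (rep in 1:50) {
    pr <- random_small_pair()
    v <- beta_pair(assemblage_pair(pr$x, pr$x), names_all, ness_m = 5)
    expect_true(all(abs(v[!is.na(v)]) < 1e-12))
  }
})

test_that("closed-form example values are reproduced", {
  expect_equal(beta("bray_curtis", assemblage_pair(c(3, 1, 0), c(1, 1, 2))),
               0.5)
  p <- assemblage_pair(c(1, 2, 3, 0), c(0, 5, 1, 4))
  mc <- matching_components(p)
  expect_equal(mc, list(a = 2L, b_u = 1L, c_u = 1L), ignore_attr = TRUE)
  expect_equal(beta("sim", p), 1 / 3)
  # identical supports and disjoint supports
  mc2 <- matching_components(assemblage_pair(c(1, 2), c(3, 4)))
  expect_equal(mc2$b_u + mc2$c_u, 0)
  mc3 <- matching_components(assemblage_pair(c(1, 0), c(0, 2)))
  expect_equal(mc3$a, 0)
})

test_that("Chao shared terms carry the unseen-species correction", {
  # all species shared with identical supports: U = V = 1, dissimilarity 0
  p <- assemblage_pair(c(5, 3, 1), c(2, 6, 4))
  ch <- chao_shared_terms(p)
  expect_equal(ch$U, 1)
  expect_equal(ch$V, 1)
  expect_equal(beta("chao_sorensen", p), 0)
  # disjoint supports: U = V = 0, dissimilarity 1
  pd <- assemblage_pair(c(3, 2, 0, 0), c(0, 0, 4, 1))
  chd <- chao_shared_terms(pd)
  expect_equal(chd$U + chd$V, 0)
  expect_equal(beta("chao_jaccard", pd), 1)
  # a shared singleton inflates U above the raw observed share
  x <- c(4, 3, 2, 1, 6, 0); y <- c(2, 1, 0, 3, 1, 5)
  ps <- assemblage_pair(x, y)
  ch2 <- chao_shared_terms(ps)
  raw_U <- sum(x[x > 0 & y > 0]) / sum(x)
  expect_gt(ch2$U, raw_U)
  expect_error(chao_shared_terms(assemblage_pair(c(0, 0), c(1, 2))),
               "zero-total")
})

test_that("partitions are additive and match the worked example", {
  p <- assemblage_pair(c(2, 2, 2), c(2, 0, 0))
  bp <- beta_partition(p, "bray_curtis", "baselga")
  expect_equal(bp$total, 0.5)
  expect_equal(bp$turnover, 0)
  expect_equal(bp$nestedness, 0.5)
  # identical pair
  pi <- assemblage_pair(c(1, 2), c(1, 2))
  expect_equal(unlist(beta_partition(pi, "ruzicka", "podani")),
               c(turnover = 0, nestedness = 0, total = 0))
  # complete turnover: the turnover component carries all dissimilarity
  pc <- assemblage_pair(c(3, 2, 0, 0), c(0, 0, 3, 2))
  for (base in c("bray_curtis", "ruzicka")) for (sch in c("baselga", "podani")) {
    bpc <- beta_partition(pc, base, sch)
    expect_equal(bpc$turnover, bpc$total, info = paste(base, sch))
  }
  # additivity against the full dissimilarity on random pairs
  set.seed(5150)
  for (rep in 1:200) {
    pr <- random_small_pair()
    pp <- assemblage_pair(pr$x, pr$y)
    for (base in c("bray_curtis", "ruzicka")) for (sch in c("baselga", "podani")) {
      b3 <- beta_partition(pp, base, sch)
      expect_equal(b3$turnover + b3$nestedness, beta(base, pp),
                   tolerance = 1e-12)
      expect_gte(b3$turnover, 0)
      expect_gte(b3$nestedness, -1e-12)
    }
  }
})

test_that("scale-invariance families hold", {
  set.seed(31)
  pa <- c("sim", "classic_sorensen", "classic_jaccard")
  rel <- c("renkonen", "horn", "morisita_horn", "jost_shannon", "jost_simpson")
  for (rep in 1:50) {
    pr <- random_small_pair()
    p0 <- assemblage_pair(pr$x, pr$y)
    p7 <- scale_abundances(p0, 7, "both")
    # presence-absence metrics: invariant to any occupancy-preserving change
    jitter <- assemblage_pair(pr$x * sample(1:5, length(pr$x), TRUE), pr$y)
    expect_equal(beta_pair(jitter, pa), beta_pair(p0, pa), tolerance = 1e-12)
    # relative-abundance metrics: invariant to common rescaling
    expect_equal(beta_pair(p7, rel), beta_pair(p0, rel), tolerance = 1e-12)
  }
})

test_that("invalid inputs are rejected", {
  p <- assemblage_pair(c(1, 2), c(2, 1))
  expect_error(beta("not_a_metric", p), "unknown metric")
  expect_error(beta_pair(p, c("sim", "nope")), "unknown metric")
  expect_error(beta("bray_curtis", assemblage_pair(c(0, 0), c(0, 0))),
               "all-zero")
})

test_that("beta_matrix computes pairwise tables in both shapes", {
  comm <- rbind(A = c(3, 1, 0, 7, 2), B = c(1, 1, 2, 0, 5),
                C = c(0, 0, 1, 1, 1))
  mats <- beta_matrix(comm, c("bray_curtis", "sim"))
  expect_equal(dim(mats$bray_curtis), c(3, 3))
  expect_equal(mats$bray_curtis["A", "B"],
               sum(abs(comm[1, ] - comm[2, ])) / sum(comm[1:2, ]))
  expect_equal(unname(diag(mats$sim)), rep(0, 3))
  lg <- beta_matrix(comm, c("bray_curtis", "sim"), long = TRUE)
  expect_equal(nrow(lg), 2 * 3)
  expect_equal(lg$value[lg$metric == "bray_curtis" & lg$assemblage_1 == "A" &
                          lg$assemblage_2 == "B"],
               mats$bray_curtis["A", "B"])
})
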