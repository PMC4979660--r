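test_that("the log-series sampler hits its target moments", {
  set.seed(101)
  A <- fisher_assemblage(100, 10000)
  expect_s3_class(A, "assemblage")
  expect_equal(A$S, 100)
  expect_true(all(A$abundances >= 1))
  expect_true(all(A$abundances == round(A$abundances)))
  # expectation check: mean realized N over draws within 10% of target
  Ns <- replicate(400, fisher_assemblage(100, 10000)$N)
  expect_lt(abs(mean(Ns) - 10000) / 10000, 0.10)
  # degenerate single-species case
  ones <- replicate(800, fisher_assemblage(1, 50)$abundances)
  expect_true(all(replicate(20, fisher_assemblage(1, 50)$S) == 1))
  expect_lt(abs(mean(ones) - 50) / 50, 0.25)
  expect_error(fisher_assemblage(100, 50), "infeasible")
})

test_that("fishers_alpha solves the log-series richness relation", {
  for (sn in list(c(100, 10000), c(300, 10000), c(10, 10000), c(5, 100))) {
    a <- fishers_alpha(sn[1], sn[2])
    expect_equal(a * log1p(sn[2] / a), sn[1], tolerance = 1e-8)
  }
})

test_that("turnover relabeling conserves abundance structure exactly", {
  set.seed(7)
  A <- fisher_assemblage(100, 10000)
  p0 <- apply_turnover(A, 0)
  expect_identical(p0$x, p0$y) # t = 0: identical pair
  expect_equal(beta_pair(p0, c("sim", "bray_curtis", "morisita")),
               c(sim = 0, bray_curtis = 0, morisita = 0))
  p1 <- apply_turnover(A, 1)
  expect_equal(matching_components(p1)$a, 0) # t = 1: no shared species
  for (t in seq(0, 1, 0.2)) {
    p <- apply_turnover(A, t)
    mc <- matching_components(p)
    expect_equal(mc$a, (1 - t) * 100)
    expect_equal(mc$b_u, t * 100)
    expect_equal(mc$c_u, t * 100)
    expect_equal(beta("sim", p), t) # closed form on equal-richness pairs
    # abundance multiset conserved
    expect_equal(sort(p$y[p$y > 0]), sort(A$abundances))
  }
})

test_that("rank decoupling is calibrated and exact at the endpoints", {
  set.seed(11)
  A <- fisher_assemblage(100, 10000)
  p_pos <- decouple_ranks(A, 1)
  expect_identical(p_pos$x, p_pos$y)
  p_neg <- decouple_ranks(A, -1)
  rk <- attr(p_neg, "ranks")
  expect_equal(rk[, 2], 101 - rk[, 1], ignore_attr = TRUE)
  expect_equal(sort(p_neg$y), sort(p_neg$x)) # same multiset
  for (r in c(-0.5, 0, 0.5)) {
    sp <- replicate(1000, {
      rk <- attr(decouple_ranks(A, r), "ranks")
      stats::cor(rk[, 1], rk[, 2])
    })
    expect_lt(abs(mean(sp) - r), 0.05)
  }
})

test_that("evenness pairs conserve N and order by b", {
  set.seed(13)
  p <- evenness_pair(100, 10000, 1)
  expect_equal(sum(p$x), sum(p$y)) # redistribution moves individuals
  expect_equal(sum(p$x), 10000)
  expect_true(all(p$y >= 1))
  # median evenness difference strictly increases as b decreases
  bs <- c(8, 2, 1, 0.2)
  dE <- vapply(bs, function(b) {
    stats::median(replicate(200, attr(evenness_pair(100, 10000, b), "delta_E")))
  }, numeric(1))
  expect_true(all(diff(dE) > 0))
  expect_gt(dE[4], 0.9) # the extreme cell approaches the maximal contrast
})

test_that("nested loss removes exactly the requested species", {
  set.seed(17)
  A <- fisher_assemblage(100, 10000)
  p0 <- nested_loss(A, 0)
  expect_identical(p0$x, p0$y)
  for (n in c(10, 50, 90)) {
    p <- nested_loss(A, n)
    expect_equal(sum(p$y > 0), 100 - n)
    expect_equal(sum(p$x > 0), 100)
  }
  expect_error(nested_loss(A, 100), "emptied")
})

test_that("species replication scales structure but not bounded metrics", {
  set.seed(19)
  A <- fisher_assemblage(50, 2000)
  p <- apply_turnover(A, 0.4)
  expect_identical(replicate_species(p, 1L), p)
  for (x in c(2L, 5L)) {
    px <- replicate_species(p, x)
    expect_equal(length(px$x), x * length(p$x))
    expect_equal(sum(px$x), x * sum(p$x))
    expect_equal(beta("sim", px), beta("sim", p)) # invariant: a,b,c scale by x
    expect_equal(beta("bray_curtis", px), beta("bray_curtis", p))
  }
})

test_that("abundance rescaling leaves occupancy untouched", {
  p <- assemblage_pair(c(3, 0, 2), c(1, 4, 0))
  pb <- scale_abundances(p, 7, "both")
  expect_equal(pb$x, 7 * p$x)
  expect_equal(pb$y, 7 * p$y)
  expect_identical(scale_abundances(p, 1, "both")$x, p$x)
  pf <- scale_abundances(p, 3, "first")
  expect_equal(pf$y, p$y)
  expect_equal(beta("renkonen", pb), beta("renkonen", p)) # relative abundances
})

test_that("subsampling is multivariate hypergeometric", {
  set.seed(23)
  A <- fisher_assemblage(100, 10000)
  expect_identical(subsample(A, A$N), A)
  s <- subsample(A, 500)
  expect_equal(s$N, 500)
  expect_true(all(s$abundances <= A$abundances))
  expect_error(subsample(A, A$N + 1), "in \\(0, N\\]")
  # hypergeometric mean of the dominant species
  dom <- which.max(A$abundances)
  n <- 2000
  draws <- replicate(2000, subsample(A, n)$abundances[dom])
  expect_lt(abs(mean(draws) - n * A$abundances[dom] / A$N) /
              (n * A$abundances[dom] / A$N), 0.02)
})

test_that("subsampling matches a brute-force urn model in distribution", {
  set.seed(29)
  ab <- c(20, 15, 8, 5, 2) # 5 species, N = 50
  A <- assemblage(paste0("s", 1:5), ab)
  n_draw <- 2000
  mine <- replicate(n_draw, subsample(A, 20)$abundances)
  urn <- replicate(n_draw, urn_subsample(ab, 20))
  # per-species totals against the exact hypergeometric expectation
  expected <- 20 * ab / 50
  expect_lt(max(abs(rowMeans(mine) - expected)), 0.25)
  expect_lt(max(abs(rowMeans(urn) - expected)), 0.25)
  # distribution of the dominant species' sampled count, lumped into bins
  # with comfortable expected counts: (i) goodness of fit of each sampler
  # against the exact hypergeometric law, (ii) homogeneity of the two
  edges <- c(-1, 6, 7, 8, 9, 10, 21)
  bin <- function(v) table(cut(v, edges))
  p_bin <- diff(stats::phyper(edges, 20, 30, 20))
  chi_mine <- stats::chisq.test(bin(mine[1, ]), p = p_bin)
  chi_urn <- stats::chisq.test(bin(urn[1, ]), p = p_bin)
  expect_gt(chi_mine$p.value, 0.001)
  expect_gt(chi_urn$p.value, 0.001)
  chi_2s <- stats::chisq.test(rbind(bin(mine[1, ]), bin(urn[1, ])))
  expect_gt(chi_2s$p.value, 0.001)
})

test_that("iid triplets give probabilistic (multiplicative) sharing", {
  set.seed(31)
  A <- fisher_assemblage(100, 10000)
  t1 <- iid_triplet(A, 1)
  expect_equal(t1$x, t1$y)
  expect_equal(t1$y, t1$z)
  t0 <- iid_triplet(A, 0)
  expect_equal(sum(t0$x > 0 & t0$y > 0), 0)
  expect_equal(sum(t0$y > 0 & t0$z > 0), 0)
  expect_equal(sum(t0$x > 0 & t0$z > 0), 0)
  # expected shared fraction between assemblages 1 and 3 is p^2
  for (p in c(0.4, 0.6)) {
    sh <- replicate(400, {
      tr <- iid_triplet(A, p)
      sum(tr$x > 0 & tr$z > 0)
    })
    expect_lt(abs(mean(sh) - p^2 * 100), 2.5)
    # step one conserves exactly round(p*S)
    tr <- iid_triplet(A, p)
    expect_equal(sum(tr$x > 0 & tr$y > 0), round(p * 100))
  }
})

test_that("gradient triplets bias the second turnover step", {
  set.seed(37)
  A <- fisher_assemblage(100, 10000)
  g1 <- gradient_triplet(A, 0, 1)
  expect_equal(g1$x, g1$y)
  # strong gradient: all second-step turnover falls on shared species,
  # so every first-step novel species survives into C
  gg <- gradient_triplet(A, 0.3, 1e8)
  novel_b <- gg$y > 0 & gg$x == 0
  expect_equal(sum(novel_b & gg$z > 0), 30)
  expect_equal(sum(gg$x > 0 & gg$z > 0), 40)
})

test_that("double entries behave as zeros or shared presences", {
  set.seed(41)
  A <- fisher_assemblage(100, 10000)
  p <- apply_turnover(A, 0.4)
  expect_identical(add_double_entries(p, 0, "zeros"), p)
  pz <- add_double_entries(p, 10, "zeros", source = A$abundances)
  expect_equal(beta("bray_curtis", pz), beta("bray_curtis", p))
  expect_equal(length(pz$x), length(p$x) + 10)
  pp <- add_double_entries(p, 10, "presences", source = A$abundances)
  expect_true(all(pp$x[seq(length(p$x) + 1, length(pp$x))] ==
                    pp$y[seq(length(p$x) + 1, length(pp$x))]))
  expect_lt(beta("bray_curtis", pp), beta("bray_curtis", p))
})

test_that("pairs drop double zeros and keep alignment", {
  A <- assemblage(c("a", "b", "c"), c(2, 3, 0))
  B <- assemblage(c("b", "d"), c(1, 5))
  p <- pair_from_assemblages(A, B)
  expect_true(all(p$x > 0 | p$y > 0))
  expect_equal(p$x[match("b", p$union_species)], 3)
  expect_equal(p$y[match("d", p$union_species)], 5)
})

test_that("assemblages and community matrices round-trip through text", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  A <- assemblage(c("sp1", "sp2"), c(10, 3))
  write_assemblage(A, tmp)
  A2 <- read_assemblage(tmp)
  expect_equal(A2$species_ids, A$species_ids)
  expect_equal(A2$abundances, A$abundances)
  comm <- rbind(A = c(3, 1, 0), B = c(1, 1, 2))
  colnames(comm) <- paste0("sp", 1:3)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_community(comm, tmp2)
  expect_equal(read_community(tmp2), comm)
})
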