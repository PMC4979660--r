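# The beta-diversity metric registry.
#
# Every metric is a pure function of an aligned abundance pair (x, y) and is
# expressed as a dissimilarity: similarity-type indices are returned as
# 1 - similarity, so larger values always mean more differentiation.
# Bounded similarity-type values are clamped to [0, 1] to absorb both
# floating-point drift and the small finite-sample excursions above 1 that
# the Morisita and Chao estimators can produce.

.PA_METRICS <- c("sim", "classic_sorensen", "classic_jaccard")
.UNBOUNDED <- c("lande_shannon", "lande_simpson", "cyd", "binomial",
                "manhattan", "av_euclidean", "euclidean", "alt_gower")
.COMPONENTS <- c("baselga_bc_turn", "baselga_r_turn",
                 "podani_bc_turn", "podani_r_turn")
.NEST_COMPONENTS <- c("baselga_bc_nest", "baselga_r_nest",
                      "podani_bc_nest", "podani_r_nest")
.BASE_METRICS <- c("morisita", "horn", "morisita_horn", "jost_simpson",
                   "renkonen", "kulczynski", "bray_curtis", "canberra",
                   "ruzicka", "ness", "sim", "classic_sorensen",
                   "classic_jaccard", "jost_shannon", "chao_sorensen",
                   "chao_jaccard", "lande_shannon", "cyd", "lande_simpson",
                   "binomial", "gower", "manhattan", "alt_gower",
                   "av_euclidean", "euclidean")

.DISPLAY_NAMES <- c(
  morisita = "Morisita", horn = "Horn", morisita_horn = "Morisita-Horn",
  jost_simpson = "Jost Simpson", renkonen = "Renkonen",
  kulczynski = "Kulczynski", bray_curtis = "Bray-Curtis",
  canberra = "Canberra", ruzicka = "Ruzicka", ness = "NESS",
  sim = "sim", classic_sorensen = "Classic Sorensen",
  classic_jaccard = "Classic Jaccard", jost_shannon = "Jost Shannon",
  chao_sorensen = "Chao Sorensen", chao_jaccard = "Chao Jaccard",
  lande_shannon = "Lande Shannon", cyd = "CYd",
  lande_simpson = "Lande Simpson", binomial = "Binomial", gower = "Gower",
  manhattan = "Manhattan", alt_gower = "alt. Gower",
  av_euclidean = "Av. Euclidean", euclidean = "Euclidean",
  baselga_bc_turn = "Baselga B-C turn", baselga_r_turn = "Baselga R turn",
  podani_bc_turn = "Podani B-C turn", podani_r_turn = "Podani R turn",
  baselga_bc_nest = "Baselga B-C nest", baselga_r_nest = "Baselga R nest",
  podani_bc_nest = "Podani B-C nest", podani_r_nest = "Podani R nest")

#' The metric registry
#'
#' Lists every implemented metric with its flags: whether it uses abundance
#' information, whether it has a fixed upper limit (bounded), and whether a
#' similarity complement `1 - beta` exists (required for the probabilistic
#' similarity property; true exactly for the bounded metrics).  The default
#' scorecard evaluates the 29 registry rows: 25 base metrics plus the four
#' partitioned turnover components; the four nestedness complements are
#' available as a convenience.
#'
#' @param include_nestedness Also list the nestedness complement components.
#' @return A data frame with columns `name`, `display`, `uses_abundance`,
#'   `bounded`, `has_similarity_complement`, `is_component`.
#' @export
metric_registry <- function(include_nestedness = FALSE) {
  nm <- c(.BASE_METRICS, .COMPONENTS,
          if (include_nestedness) .NEST_COMPONENTS)
  data.frame(
    name = nm,
    display = unname(.DISPLAY_NAMES[nm]),
    uses_abundance = !(nm %in% .PA_METRICS),
    bounded = !(nm %in% .UNBOUNDED),
    has_similarity_complement = !(nm %in% .UNBOUNDED),
    is_component = nm %in% c(.COMPONENTS, .NEST_COMPONENTS),
    stringsAsFactors = FALSE)
}

#' Presence-absence matching components
#'
#' Counts of species shared (`a`), unique to the first assemblage (`b_u`)
#' and unique to the second (`c_u`), from strict positivity of the aligned
#' abundance vectors.
#'
#' @param pair An `"assemblage_pair"`.
#' @return A list with elements `a`, `b_u`, `c_u`.
#' @export
matching_components <- function(pair) {
  sx <- pair$x > 0; sy <- pair$y > 0
  list(a = sum(sx & sy), b_u = sum(sx & !sy), c_u = sum(sy & !sx))
}

#' Chao shared-abundance terms with the unseen-species correction
#'
#' Computes `U` (the estimated total relative abundance in the first
#' assemblage of species shared with the second, including the correction
#' for shared species likely present but unseen) and the symmetric `V`,
#' following the Chao abundance-based estimator: the observed shared
#' relative abundance plus a term built from shared species observed
#' exactly once or twice in the other assemblage.  Both are clamped to
#' \[0, 1\].
#'
#' @param pair An `"assemblage_pair"` with positive totals.
#' @return A list with `U`, `V` and the rare-shared counts
#'   `f1x`, `f2x`, `f1y`, `f2y`.
#' @export
chao_shared_terms <- function(pair) {
  x <- pair$x; y <- pair$y
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) stop("zero-total assemblage")
  sh <- x > 0 & y > 0
  f1y <- sum(sh & y == 1); f2y <- sum(sh & y == 2)
  f1x <- sum(sh & x == 1); f2x <- sum(sh & x == 2)
  U <- sum(x[sh]) / X +
    (Y - 1) / Y * f1y / (2 * max(f2y, 1)) * sum(x[sh & y == 1]) / X
  V <- sum(y[sh]) / Y +
    (X - 1) / X * f1x / (2 * max(f2x, 1)) * sum(y[sh & x == 1]) / Y
  list(U = min(max(U, 0), 1), V = min(max(V, 0), 1),
       f1x = f1x, f2x = f2x, f1y = f1y, f2y = f2y)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.clamp01 <- function(v) min(max(v, 0), 1)

# Core evaluator: computes the requested metrics for one aligned pair.
# Returns a named numeric vector; NA where a metric is undefined for the
# input (e.g. Morisita on communities of singletons, NESS on samples
# smaller than m).
.beta_core <- function(x, y, metrics, ness_m = 10) {
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) stop("beta is undefined on an all-zero assemblage")
  px <- x / X; qy <- y / Y
  sx <- x > 0; sy <- y > 0
  shared <- sx & sy
  a <- sum(shared); bu <- sum(sx & !sy); cu <- sum(sy & !sx)
  nz <- sx | sy
  NZ <- sum(nz)
  W <- sum(pmin(x, y))
  absd <- sum(abs(x - y))
  Bc <- X - W; Cc <- Y - W         # abundance gain/loss components
  minBC <- min(Bc, Cc)
  out <- stats::setNames(rep(NA_real_, length(metrics)), metrics)

  chao_uv <- NULL # computed at most once, shared by both Chao metrics
  get_chao <- function() {
    if (is.null(chao_uv)) chao_uv <<- chao_shared_terms(new_pair(NULL, x, y))
    chao_uv
  }
  for (nm in metrics) {
    out[nm] <- switch(nm,
      sim = {
        m <- min(bu, cu)
        if (m + a == 0) 0 else m / (m + a)
      },
      classic_sorensen = if (2 * a + bu + cu == 0) 0 else
        (bu + cu) / (2 * a + bu + cu),
      classic_jaccard = if (a + bu + cu == 0) 0 else
        (bu + cu) / (a + bu + cu),
      bray_curtis = absd / (X + Y),
      ruzicka = absd / (W + absd),
      renkonen = .clamp01(1 - sum(pmin(px, qy))),
      kulczynski = .clamp01(1 - 0.5 * (W / X + W / Y)),
      morisita = {
        num <- 2 * sum(x * y)
        if (num == 0) 1
        else if (X <= 1 || Y <= 1) NA_real_
        else {
          den <- (sum(x * (x - 1)) / (X * (X - 1)) +
                  sum(y * (y - 1)) / (Y * (Y - 1))) * X * Y
          if (den <= 0) NA_real_ else .clamp01(1 - num / den)
        }
      },
      morisita_horn = {
        den <- sum(px^2) + sum(qy^2)
        .clamp01(1 - 2 * sum(px * qy) / den)
      },
      horn = {
        z <- px + qy
        num <- sum(z[z > 0] * log(z[z > 0])) -
          sum(px[sx] * log(px[sx])) - sum(qy[sy] * log(qy[sy]))
        .clamp01(1 - num / (2 * log(2)))
      },
      jost_shannon = {
        m <- (px + qy) / 2
        max(exp(.entropy(m) - (.entropy(px) + .entropy(qy)) / 2) - 1, 0)
      },
      jost_simpson = {
        m <- (px + qy) / 2
        gam <- 1 / sum(m^2)
        alp <- 2 / (sum(px^2) + sum(qy^2))
        .clamp01(gam / alp - 1)
      },
      lande_shannon = {
        # additive partition: gamma on the pooled individuals, alpha as the
        # unweighted mean over assemblages
        pool <- (x + y) / (X + Y)
        max(.entropy(pool) - (.entropy(px) + .entropy(qy)) / 2, 0)
      },
      lande_simpson = {
        pool <- (x + y) / (X + Y)
        max((1 - sum(pool^2)) -
              ((1 - sum(px^2)) + (1 - sum(qy^2))) / 2, 0)
      },
      canberra = mean(abs(x[nz] - y[nz]) / (x[nz] + y[nz])),
      gower = sum(abs(x - y) > 0) / length(x),
      alt_gower = absd / NZ,
      manhattan = absd,
      euclidean = sqrt(sum((x - y)^2)),
      av_euclidean = sqrt(sum((x - y)^2) / NZ),
      binomial = {
        n <- (x + y)[nz]
        xi <- x[nz]; yi <- y[nz]
        tx <- numeric(length(n)); ty <- tx
        px0 <- xi > 0; py0 <- yi > 0
        tx[px0] <- xi[px0] * log(xi[px0] / n[px0])
        ty[py0] <- yi[py0] * log(yi[py0] / n[py0])
        sum((tx + ty + n * log(2)) / n)
      },
      cyd = {
        xx <- x[nz]; yy <- y[nz]
        xx[xx == 0] <- 0.1; yy[yy == 0] <- 0.1
        n <- xx + yy
        mean(log(n / 2) - (xx * log(yy) + yy * log(xx)) / n)
      },
      ness = {
        if (X < ness_m || Y < ness_m) NA_real_
        else {
          # detection probability of each species in a sample of m
          # individuals; species with fewer than m absentees are certain
          PA <- 1 - exp(lchoose(X - x, ness_m) - lchoose(X, ness_m))
          PA[X - x < ness_m] <- 1
          PB <- 1 - exp(lchoose(Y - y, ness_m) - lchoose(Y, ness_m))
          PB[Y - y < ness_m] <- 1
          den <- sum(PA^2) + sum(PB^2)
          if (den == 0) NA_real_ else .clamp01(1 - 2 * sum(PA * PB) / den)
        }
      },
      chao_sorensen = {
        ch <- get_chao()
        if (ch$U + ch$V == 0) 1 else
          .clamp01(1 - 2 * ch$U * ch$V / (ch$U + ch$V))
      },
      chao_jaccard = {
        ch <- get_chao()
        if (ch$U + ch$V == 0) 1 else
          .clamp01(1 - ch$U * ch$V / (ch$U + ch$V - ch$U * ch$V))
      },
      baselga_bc_turn = if (minBC == 0) 0 else minBC / (W + minBC),
      baselga_bc_nest = {
        tot <- if (X + Y == 0) 0 else absd / (X + Y)
        turn <- if (minBC == 0) 0 else minBC / (W + minBC)
        tot - turn
      },
      baselga_r_turn = if (minBC == 0) 0 else 2 * minBC / (W + 2 * minBC),
      baselga_r_nest = {
        tot <- if (W + absd == 0) 0 else absd / (W + absd)
        turn <- if (minBC == 0) 0 else 2 * minBC / (W + 2 * minBC)
        tot - turn
      },
      podani_bc_turn = 2 * minBC / (X + Y),
      podani_bc_nest = abs(Bc - Cc) / (X + Y),
      podani_r_turn = 2 * minBC / (W + absd + (W + absd == 0)),
      podani_r_nest = abs(Bc - Cc) / (W + absd + (W + absd == 0)),
      stop("unknown metric name: ", nm)
    )
  }
  out
}

#' Compute a beta-diversity metric on a pair
#'
#' @param name A registry metric name (see [metric_registry]).
#' @param pair An `"assemblage_pair"`.
#' @param ness_m Sample-size parameter of the NESS index.
#' @return The dissimilarity value (scalar); `NA` if the metric is
#'   undefined for this input.
#' @export
beta <- function(name, pair, ness_m = 10) {
  if (!name %in% c(.BASE_METRICS, .COMPONENTS, .NEST_COMPONENTS))
    stop("unknown metric name: ", name)
  unname(.beta_core(pair$x, pair$y, name, ness_m = ness_m))
}

#' Compute many metrics on one pair
#'
#' @param pair An `"assemblage_pair"`.
#' @param metrics Character vector of registry names (default: the 29
#'   scorecard metrics).
#' @param ness_m Sample-size parameter of the NESS index.
#' @return Named numeric vector of dissimilarities.
#' @export
beta_pair <- function(pair, metrics = metric_registry()$name, ness_m = 10) {
  bad <- setdiff(metrics, c(.BASE_METRICS, .COMPONENTS, .NEST_COMPONENTS))
  if (length(bad)) stop("unknown metric name(s): ", paste(bad, collapse = ", "))
  .beta_core(pair$x, pair$y, metrics, ness_m = ness_m)
}

#' Turnover/nestedness partition of Bray-Curtis or Ruzicka dissimilarity
#'
#' Additively partitions the total dissimilarity into a turnover
#' (balanced-variation / replacement) component and a nestedness
#' (abundance-gradient / richness-difference) component, following either
#' the Baselga or the Podani school.
#'
#' @param pair An `"assemblage_pair"`.
#' @param base `"bray_curtis"` or `"ruzicka"`.
#' @param scheme `"baselga"` or `"podani"`.
#' @return A list with `turnover`, `nestedness` and `total`
#'   (`turnover + nestedness == total`).
#' @export
beta_partition <- function(pair, base = c("bray_curtis", "ruzicka"),
                           scheme = c("baselga", "podani")) {
  base <- match.arg(base); scheme <- match.arg(scheme)
  code <- paste0(if (scheme == "baselga") "baselga_" else "podani_",
                 if (base == "bray_curtis") "bc" else "r")
  v <- .beta_core(pair$x, pair$y,
                  c(paste0(code, "_turn"), paste0(code, "_nest"), base))
  list(turnover = unname(v[1]), nestedness = unname(v[2]),
       total = unname(v[1] + v[2]))
}

#' Pairwise dissimilarities for a community matrix
#'
#' Applies registry metrics to every pair of rows of a community matrix
#' (assemblages in rows, species in columns).
#'
#' @param comm Non-negative matrix, assemblages in rows.
#' @param metrics Registry names.
#' @param long If `TRUE` return a long data frame
#'   (`assemblage_1`, `assemblage_2`, `metric`, `value`); otherwise a named
#'   list of square symmetric matrices, one per metric.
#' @param ness_m Sample-size parameter of the NESS index.
#' @return See `long`.
#' @export
beta_matrix <- function(comm, metrics = metric_registry()$name,
                        long = FALSE, ness_m = 10) {
  comm <- as.matrix(comm)
  n <- nrow(comm)
  rn <- rownames(comm)
  if (is.null(rn)) rn <- paste0("A", seq_len(n))
  mats <- lapply(metrics, function(m) {
    M <- matrix(0, n, n, dimnames = list(rn, rn))
    M
  })
  names(mats) <- metrics
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- .beta_core(comm[i, ], comm[j, ], metrics, ness_m = ness_m)
    for (m in metrics) mats[[m]][i, j] <- mats[[m]][j, i] <- v[[m]]
  }
  if (!long) return(mats)
  do.call(rbind, lapply(metrics, function(m) {
    idx <- which(upper.tri(mats[[m]]), arr.ind = TRUE)
    data.frame(assemblage_1 = rn[idx[, 1]], assemblage_2 = rn[idx[, 2]],
               metric = m, value = mats[[m]][idx],
               stringsAsFactors = FALSE)
  }))
}
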