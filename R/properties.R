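# Property evaluations: conceptual (C1-C16), sampling (S1-S2) and
# personality (P1-P5) tests of every registry metric, driven by Monte-Carlo
# simulation over manipulated assemblages.
#
# Each simulation cell is run n_reps times on a freshly drawn starting
# assemblage; the cell statistic is the median dissimilarity over
# replicates (replicates on which a metric is undefined are excluded from
# that metric's median, with a logged count).  Before quantitative scoring,
# every metric's cell medians are rescaled relative to the maximum value
# attained in that property's simulation set, putting bounded and
# unbounded metrics on a comparable [0, 1] scale.

.PROPERTY_IDS <- c(paste0("C", 1:16), "S1", "S2", paste0("P", 1:5))

.QUALITATIVE <- c("C4", "C5", "C6", "C7", "C8", "C9", "C10", "C11", "C12", "C13")
.QUANTITATIVE <- c("C1", "C2", "C3", "C14", "C15", "C16", "S1", "S2")
.PERSONALITY <- c("P1", "P2", "P3", "P4", "P5")

.derive_seed <- function(seed, ...) {
  s <- as.double(seed %% 2147483647L)
  for (k in c(...)) s <- (s * 69069 + k * 2654435.761) %% 2147483647
  as.integer(floor(s))
}

#' Rescale cell medians relative to their maximum
#'
#' Divides a set of medians by the maximum value attained in the set, so
#' the maximum maps to 1 and all values lie in \[0, 1\].  An all-zero set
#' is returned unchanged.
#'
#' @param x Numeric vector (or matrix whose columns are rescaled
#'   independently) of cell medians.
#' @return Rescaled values on the same shape.
#' @export
rescale_to_max <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, rescale_to_max))
  mx <- max(x, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) return(x)
  x / mx
}

# Median over n_reps calls of fn() (a fresh simulation each time), per
# output coordinate, NA-excluded with counts.
.mc_medians <- function(n_reps, seed, fn, n_out) {
  set.seed(seed)
  acc <- vapply(seq_len(n_reps), function(i) fn(), numeric(n_out))
  if (n_out == 1L) acc <- matrix(acc, nrow = 1L)
  list(median = apply(acc, 1, stats::median, na.rm = TRUE),
       na = rowSums(is.na(acc)))
}

# Run a grid of cells; fn(cell) must return a numeric vector of length
# n_out each call.  Returns medians (cells x n_out) and NA counts.
.run_grid <- function(cells, n_reps, seed, prop_idx, fn, n_out) {
  med <- matrix(NA_real_, nrow(cells), n_out)
  nac <- matrix(0, nrow(cells), n_out)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    r <- .mc_medians(n_reps, .derive_seed(seed, prop_idx, ci),
                     function() fn(cell), n_out)
    med[ci, ] <- r$median
    nac[ci, ] <- r$na
  }
  list(median = med, na = nac)
}

.rmse <- function(err) sqrt(mean(err^2))

.new_property <- function(id, kind, scores, cells, seed, n_reps, na_total) {
  structure(list(property_id = id, kind = kind, scores = scores,
                 cells = cells, seed = seed, n_reps = n_reps,
                 na_total = na_total),
            class = "bb_property")
}

#' @export
print.bb_property <- function(x, ...) {
  cat(sprintf("Property %s (%s), n_reps = %d, seed = %d\n",
              x$property_id, x$kind, x$n_reps, x$seed))
  print(x$scores)
  invisible(x)
}

# ---- individual property runners ------------------------------------------

# Within every replicate the turnover levels are applied to one shared
# starting assemblage (a paired design: between-assemblage variance
# cancels out of the cell-to-cell contrasts).
.prop_C1 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     t_levels = seq(0, 1, 0.2),
                     S_levels = c(300, 250, 200, 150, 100, 80, 60, 40, 20, 10)) {
  nm <- length(metrics); nt <- length(t_levels)
  outer_cells <- data.frame(S_level = S_levels)
  r <- .run_grid(outer_cells, n_reps, seed, 1L, function(cell) {
    A <- fisher_assemblage(cell$S_level, N)
    out <- numeric(nt * nm)
    for (ti in seq_len(nt))
      out[(ti - 1L) * nm + seq_len(nm)] <-
        beta_pair(apply_turnover(A, t_levels[ti]), metrics)
    out
  }, nt * nm)
  cells <- expand.grid(S_level = S_levels, t = t_levels)
  med <- matrix(NA_real_, nrow(cells), nm)
  for (ti in seq_len(nt))
    med[cells$t == t_levels[ti], ] <-
      r$median[, (ti - 1L) * nm + seq_len(nm), drop = FALSE]
  resc <- rescale_to_max(med)
  base <- cells$S_level == max(S_levels)
  scores <- vapply(seq_len(nm), function(j) {
    err <- vapply(which(!base), function(i) {
      resc[i, j] - resc[base & cells$t == cells$t[i], j]
    }, numeric(1))
    .rmse(err)
  }, numeric(1))
  names(scores) <- metrics
  cdf <- data.frame(cells[rep(seq_len(nrow(cells)), nm), ],
                    metric = rep(metrics, each = nrow(cells)),
                    median_beta = as.vector(med),
                    rescaled = as.vector(resc), row.names = NULL)
  .new_property("C1", "quantitative", scores, cdf, seed, n_reps, sum(r$na))
}

# shared engine for the triplet properties C2 (gradient) and C3 (iid draws)
.prop_triplet <- function(id, metrics, n_reps, seed, prop_idx, cells, maker,
                          probabilistic) {
  nm <- length(metrics)
  r <- .run_grid(cells, n_reps, seed, prop_idx, function(cell) {
    trip <- maker(cell)
    c(beta_pair(triplet_pair(trip, "AB"), metrics),
      beta_pair(triplet_pair(trip, "BC"), metrics),
      beta_pair(triplet_pair(trip, "AC"), metrics))
  }, 3L * nm)
  reg <- metric_registry(include_nestedness = TRUE)
  scores <- vector("list", nm)
  names(scores) <- metrics
  for (j in seq_len(nm)) {
    m3 <- r$median[, c(j, j + nm, j + 2L * nm), drop = FALSE]
    m3 <- m3 / max(m3, 1e-300) # rescale within the metric's simulation set
    if (probabilistic) {
      if (!reg$has_similarity_complement[match(metrics[j], reg$name)]) {
        scores[[j]] <- FALSE
        next
      }
      err <- (1 - m3[, 3]) - (1 - m3[, 1]) * (1 - m3[, 2])
    } else {
      err <- m3[, 3] - (m3[, 1] + m3[, 2])
    }
    scores[[j]] <- .rmse(err)
  }
  cdf <- data.frame(cells[rep(seq_len(nrow(cells)), 3L * nm), , drop = FALSE],
                    series = rep(c("AB", "BC", "AC"),
                                 each = nm * nrow(cells)),
                    metric = rep(rep(metrics, each = nrow(cells)), times = 3L),
                    median_beta = as.vector(r$median), row.names = NULL)
  .new_property(id, "quantitative", scores, cdf, seed, n_reps, sum(r$na))
}

.prop_C2 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     t_levels = seq(0, 0.5, 0.1),
                     g_levels = c(1, 5, 10, 50, 100, 500, 1000)) {
  cells <- expand.grid(t = t_levels, g = g_levels)
  .prop_triplet("C2", metrics, n_reps, seed, 2L, cells, function(cell) {
    gradient_triplet(fisher_assemblage(S, N), cell$t, cell$g)
  }, probabilistic = FALSE)
}

.prop_C3 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     p_levels = seq(0, 1, 0.2)) {
  cells <- data.frame(p = p_levels)
  .prop_triplet("C3", metrics, n_reps, seed, 3L, cells, function(cell) {
    iid_triplet(fisher_assemblage(S, N), cell$p)
  }, probabilistic = TRUE)
}

.prop_C4 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  set.seed(.derive_seed(seed, 4L, 1L))
  n_check <- max(10L, min(n_reps, 50L))
  ok_zero <- rep(TRUE, length(metrics))
  ok_pos <- rep(TRUE, length(metrics))
  for (i in seq_len(n_check)) {
    A <- fisher_assemblage(S, N)
    ident <- new_pair(A$species_ids, A$abundances, A$abundances)
    v <- beta_pair(ident, metrics)
    ok_zero <- ok_zero & (is.na(v) | abs(v) < 1e-12)
    for (pair in list(apply_turnover(A, stats::runif(1)),
                      decouple_ranks(A, stats::runif(1, -1, 1)),
                      evenness_pair(S, N, stats::runif(1, 0.2, 8)))) {
      v <- beta_pair(pair, metrics)
      ok_pos <- ok_pos & (is.na(v) | v > -1e-12)
    }
  }
  scores <- stats::setNames(as.list(ok_zero & ok_pos), metrics)
  .new_property("C4", "qualitative", scores, NULL, seed, n_reps, 0L)
}

# C5: a metric has a fixed upper limit when it attains the conventional
# maximum of 1 on every completely distinct pair, invariantly across
# draws, common abundance rescaling and species replication.  Metrics
# whose value at complete differentiation depends on the data (total
# abundance, richness, evenness) have no fixed limit.
.prop_C5 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  set.seed(.derive_seed(seed, 5L, 1L))
  ok <- rep(TRUE, length(metrics))
  for (i in 1:5) {
    A <- fisher_assemblage(S, N)
    disjoint <- apply_turnover(A, 1) # no shared species
    variants <- list(disjoint,
                     scale_abundances(disjoint, 10, "both"),
                     replicate_species(disjoint, 10L))
    for (vpair in variants) {
      v <- beta_pair(vpair, metrics)
      ok <- ok & (is.na(v) | abs(v - 1) < 1e-9)
    }
  }
  scores <- stats::setNames(as.list(ok), metrics)
  .new_property("C5", "qualitative", scores, NULL, seed, n_reps, 0L)
}

# Monotonicity properties use a paired design: within each replicate all
# grid levels are applied to the same starting assemblage, so the
# level-to-level contrasts are free of between-assemblage noise.
.prop_monotone_series <- function(id, metrics, n_reps, seed, prop_idx,
                                  levels_df, pair_fn, strict = TRUE,
                                  extra_stat = FALSE) {
  nm <- length(metrics); nl <- nrow(levels_df)
  width <- nl * (nm + extra_stat)
  r <- .run_grid(data.frame(cell = 1L), n_reps, seed, prop_idx, function(cell) {
    ctx <- new.env(parent = emptyenv())
    out <- numeric(width)
    for (li in seq_len(nl)) {
      pair <- pair_fn(levels_df[li, , drop = FALSE], ctx)
      v <- beta_pair(pair, metrics)
      if (extra_stat) v <- c(v, attr(pair, "delta_E"))
      out[(li - 1L) * (nm + extra_stat) + seq_len(nm + extra_stat)] <- v
    }
    out
  }, width)
  med <- matrix(r$median, nrow = nl, byrow = TRUE)
  list(median = med[, seq_len(nm), drop = FALSE],
       extra = if (extra_stat) med[, nm + 1L] else NULL,
       na = sum(r$na))
}

.prop_C6 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     t_levels = seq(0, 1, 0.2)) {
  r <- .prop_monotone_series("C6", metrics, n_reps, seed, 6L,
    data.frame(t = t_levels),
    function(lev, ctx) {
      if (is.null(ctx$A)) ctx$A <- fisher_assemblage(S, N)
      apply_turnover(ctx$A, lev$t)
    })
  scores <- stats::setNames(
    lapply(seq_along(metrics), function(j) all(diff(r$median[, j]) > 1e-12)),
    metrics)
  cdf <- data.frame(t = rep(t_levels, length(metrics)),
                    metric = rep(metrics, each = length(t_levels)),
                    median_beta = as.vector(r$median), row.names = NULL)
  .new_property("C6", "qualitative", scores, cdf, seed, n_reps, r$na)
}

.prop_C7 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     r_levels = seq(1, -1, -0.1)) {
  r <- .prop_monotone_series("C7", metrics, n_reps, seed, 7L,
    data.frame(r = r_levels),
    function(lev, ctx) {
      if (is.null(ctx$A)) {
        ctx$A <- fisher_assemblage(S, N)
        ctx$noise <- stats::rnorm(S)
      }
      # shared noise couples the r levels: the decoupling deepens
      # smoothly within a replicate as r decreases
      decouple_ranks(ctx$A, lev$r, noise = ctx$noise)
    })
  # r_levels run from +1 down to -1: median beta must rise at every step
  scores <- stats::setNames(
    lapply(seq_along(metrics), function(j) all(diff(r$median[, j]) > 1e-12)),
    metrics)
  cdf <- data.frame(r = rep(r_levels, length(metrics)),
                    metric = rep(metrics, each = length(r_levels)),
                    median_beta = as.vector(r$median), row.names = NULL)
  .new_property("C7", "qualitative", scores, cdf, seed, n_reps, r$na)
}

.prop_C8 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     b_levels = c(8, 6, 4, 2, 1.8, 1.6, 1.4, 1.2, 1,
                                  0.8, 0.6, 0.4, 0.2)) {
  r <- .prop_monotone_series("C8", metrics, n_reps, seed, 8L,
    data.frame(b = b_levels),
    function(lev, ctx) {
      if (is.null(ctx$w)) {
        alpha <- fishers_alpha(S, N)
        ctx$w <- .rlogseries(S, N / (N + alpha))
      }
      evenness_pair(S, N, lev$b, weights = ctx$w)
    },
    extra_stat = TRUE)
  dE <- r$extra
  ord <- order(dE) # score monotonicity along realized evenness difference
  scores <- stats::setNames(
    lapply(seq_along(metrics), function(j) all(diff(r$median[ord, j]) > 1e-12)),
    metrics)
  cdf <- data.frame(b = rep(b_levels, length(metrics)),
                    delta_E = rep(dE, length(metrics)),
                    metric = rep(metrics, each = length(b_levels)),
                    median_beta = as.vector(r$median),
                    row.names = NULL)
  .new_property("C8", "qualitative", scores, cdf, seed, n_reps, r$na)
}

# C9 / C10: beta at an extreme abundance difference must stay below beta at
# complete species turnover.  The turnover reference is built from the same
# replicate community (same abundance multiset and total) so the comparison
# is per-draw deterministic rather than a race between two noisy medians.
.prop_extreme_vs_turnover <- function(id, metrics, n_reps, seed, prop_idx,
                                      both_fn) {
  nm <- length(metrics)
  r <- .mc_medians(n_reps, .derive_seed(seed, prop_idx, 1L), function() {
    pr <- both_fn()
    c(beta_pair(pr$extreme, metrics), beta_pair(pr$reference, metrics))
  }, 2L * nm)
  ext <- r$median[seq_len(nm)]
  tot <- r$median[nm + seq_len(nm)]
  scores <- stats::setNames(as.list(ext < tot - 1e-12), metrics)
  cells <- data.frame(metric = metrics, median_extreme = ext,
                      median_turnover = tot)
  .new_property(id, "qualitative", scores, cells, seed, n_reps, sum(r$na))
}

# complete-turnover pair of the community holding abundance vector ab
.full_turnover_of <- function(ab) {
  ab <- ab[ab > 0]
  k <- length(ab)
  new_pair(paste0("s", seq_len(2 * k)), c(ab, numeric(k)), c(numeric(k), ab))
}

.prop_C9 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  .prop_extreme_vs_turnover("C9", metrics, n_reps, seed, 9L, function() {
    A <- fisher_assemblage(S, N)
    list(extreme = decouple_ranks(A, -1),
         reference = .full_turnover_of(A$abundances))
  })
}

.prop_C10 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  .prop_extreme_vs_turnover("C10", metrics, n_reps, seed, 10L, function() {
    pr <- evenness_pair(S, N, 0.2) # the largest realized evenness difference
    list(extreme = pr, reference = .full_turnover_of(pr$y))
  })
}

.prop_C11 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  set.seed(.derive_seed(seed, 11L, 1L))
  n_check <- max(10L, min(n_reps, 50L))
  ok <- rep(TRUE, length(metrics))
  for (i in seq_len(n_check)) {
    A <- fisher_assemblage(S, N)
    for (pair in list(apply_turnover(A, stats::runif(1)),
                      decouple_ranks(A, stats::runif(1, -1, 1)),
                      evenness_pair(S, N, stats::runif(1, 0.2, 8)))) {
      v1 <- beta_pair(pair, metrics)
      v2 <- beta_pair(new_pair(pair$union_species, pair$y, pair$x), metrics)
      ok <- ok & ((is.na(v1) & is.na(v2)) |
                    (!is.na(v1) & !is.na(v2) & abs(v1 - v2) < 1e-12))
    }
  }
  scores <- stats::setNames(as.list(ok), metrics)
  .new_property("C11", "qualitative", scores, NULL, seed, n_reps, 0L)
}

.prop_C12 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                      t_levels = c(0.2, 0.4, 0.6, 0.8), k_max = 10L) {
  nm <- length(metrics)
  nk <- k_max + 1L
  cells <- expand.grid(t = t_levels, kind = c("zeros", "presences"),
                       stringsAsFactors = FALSE)
  r <- .run_grid(cells, n_reps, seed, 12L, function(cell) {
    A <- fisher_assemblage(S, N)
    pair <- apply_turnover(A, cell$t)
    out <- numeric(nk * nm)
    for (k in 0:k_max) {
      if (k > 0)
        pair <- add_double_entries(pair, 1L, cell$kind, source = A$abundances)
      out[k * nm + seq_len(nm)] <- beta_pair(pair, metrics)
    }
    out
  }, nk * nm)
  scores <- stats::setNames(vector("list", nm), metrics)
  for (j in seq_len(nm)) {
    ok <- TRUE
    for (ci in seq_len(nrow(cells))) {
      series <- r$median[ci, j + nm * (0:k_max)]
      ok <- ok && if (cells$kind[ci] == "zeros")
        all(abs(series - series[1]) < 1e-9)
      else
        all(diff(series) < -1e-12)
    }
    scores[[j]] <- ok
  }
  .new_property("C12", "qualitative", scores, NULL, seed, n_reps, sum(r$na))
}

# Nested-loss medians on a paired design: one starting assemblage per
# replicate, one turnover relabeling per t level, and a single random
# species ordering per t so that successive loss levels form genuinely
# nested assemblages.
.nested_loss_medians <- function(metrics, n_reps, seed, prop_idx,
                                 loss_levels, t_levels, S, N) {
  nm <- length(metrics)
  cells <- expand.grid(loss = loss_levels, t = t_levels)
  width <- nrow(cells) * nm
  r <- .run_grid(data.frame(cell = 1L), n_reps, seed, prop_idx,
                 function(cell) {
    A <- fisher_assemblage(S, N)
    out <- numeric(width)
    i <- 0L
    for (tv in t_levels) {
      k <- round(tv * A$S)
      ids_b <- A$species_ids
      if (k > 0) ids_b[sample.int(A$S, k)] <- .novel_ids(k, "nvB")
      perm <- sample.int(A$S)
      for (L in loss_levels) {
        ab_b <- A$abundances
        if (L > 0) ab_b[perm[seq_len(L)]] <- 0
        out[i * nm + seq_len(nm)] <-
          beta_pair(pair_from_assemblages(A, assemblage(ids_b, ab_b)),
                    metrics)
        i <- i + 1L
      }
    }
    out
  }, width)
  med <- matrix(r$median, nrow = nrow(cells), byrow = TRUE)
  list(median = med, cells = cells, na = sum(r$na))
}

# tol separates genuine declines under nestedness (rescaled dips of 0.03
# and larger for the turnover components and distance-type metrics) from
# Monte-Carlo wobble on flat series (below 0.006 at n_reps >= 200)
.prop_C13 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                      loss_levels = seq(0, 90, 10),
                      t_levels = seq(0, 1, 0.2), tol = 0.02) {
  r <- .nested_loss_medians(metrics, n_reps, seed, 13L, loss_levels,
                            t_levels, S, N)
  cells <- r$cells
  resc <- rescale_to_max(r$median)
  scores <- stats::setNames(lapply(seq_along(metrics), function(j) {
    ok <- TRUE
    for (tv in t_levels) {
      series <- resc[cells$t == tv, j][order(cells$loss[cells$t == tv])]
      ok <- ok && all(diff(series) >= -tol)
    }
    ok
  }), metrics)
  cdf <- data.frame(cells[rep(seq_len(nrow(cells)), length(metrics)), ],
                    metric = rep(metrics, each = nrow(cells)),
                    median_beta = as.vector(r$median), row.names = NULL)
  .new_property("C13", "qualitative", scores, cdf, seed, n_reps, r$na)
}

# shared engine for the paired-transform RMSE properties C14/C15/C16
.prop_transform <- function(id, metrics, n_reps, seed, prop_idx, factors,
                            transform, S = 100, N = 10000,
                            t_levels = seq(0, 1, 0.2)) {
  nm <- length(metrics)
  nf <- length(factors)
  cells <- data.frame(t = t_levels)
  r <- .run_grid(cells, n_reps, seed, prop_idx, function(cell) {
    pair <- apply_turnover(fisher_assemblage(S, N), cell$t)
    out <- numeric(nf * nm)
    for (fi in seq_len(nf))
      out[(fi - 1L) * nm + seq_len(nm)] <-
        beta_pair(transform(pair, factors[fi]), metrics)
    out
  }, nf * nm)
  scores <- numeric(nm)
  full <- expand.grid(t = t_levels, factor = factors)
  med_long <- matrix(NA_real_, nrow(full), nm)
  for (fi in seq_len(nf))
    med_long[full$factor == factors[fi], ] <-
      r$median[, (fi - 1L) * nm + seq_len(nm), drop = FALSE]
  resc <- rescale_to_max(med_long)
  for (j in seq_len(nm)) {
    err <- vapply(which(full$factor != factors[1]), function(i) {
      resc[i, j] - resc[full$factor == factors[1] & full$t == full$t[i], j]
    }, numeric(1))
    scores[j] <- .rmse(err)
  }
  names(scores) <- metrics
  cdf <- data.frame(full[rep(seq_len(nrow(full)), nm), ],
                    metric = rep(metrics, each = nrow(full)),
                    median_beta = as.vector(med_long),
                    rescaled = as.vector(resc), row.names = NULL)
  .new_property(id, "quantitative", scores, cdf, seed, n_reps, sum(r$na))
}

.prop_C14 <- function(metrics, n_reps, seed, ...) {
  .prop_transform("C14", metrics, n_reps, seed, 14L, 1:10,
                  function(pair, f) replicate_species(pair, as.integer(f)), ...)
}

.prop_C15 <- function(metrics, n_reps, seed, ...) {
  .prop_transform("C15", metrics, n_reps, seed, 15L, 1:10,
                  function(pair, f) scale_abundances(pair, f, "both"), ...)
}

.prop_C16 <- function(metrics, n_reps, seed, ...) {
  .prop_transform("C16", metrics, n_reps, seed, 16L, 1:10,
                  function(pair, f) scale_abundances(pair, f, "first"), ...)
}

# sampling properties: subsample the pair, score drift from the full census
.prop_sampling <- function(id, metrics, n_reps, seed, prop_idx, sizes,
                           both_sides, S = 100, N = 10000,
                           t_levels = seq(0, 1, 0.2)) {
  nm <- length(metrics)
  ns <- length(sizes)
  cells <- data.frame(t = t_levels)
  side_assemblage <- function(pair, col) {
    assemblage(pair$union_species, pair[[col]])
  }
  r <- .run_grid(cells, n_reps, seed, prop_idx, function(cell) {
    pair <- apply_turnover(fisher_assemblage(S, N), cell$t)
    Ax <- side_assemblage(pair, "x"); Ay <- side_assemblage(pair, "y")
    out <- numeric(ns * nm)
    for (si in seq_len(ns)) {
      if (both_sides) {
        n_eff <- min(sizes[si], Ax$N, Ay$N)
        sp <- new_pair(pair$union_species,
                       subsample(Ax, n_eff)$abundances,
                       subsample(Ay, n_eff)$abundances)
      } else {
        n_eff <- max(Ay$N - sizes[si], 1)
        sp <- if (n_eff >= Ay$N) pair else
          new_pair(pair$union_species, pair$x, subsample(Ay, n_eff)$abundances)
      }
      keep <- sp$x > 0 | sp$y > 0
      out[(si - 1L) * nm + seq_len(nm)] <-
        beta_pair(new_pair(sp$union_species[keep], sp$x[keep], sp$y[keep]),
                  metrics)
    }
    out
  }, ns * nm)
  full <- expand.grid(t = t_levels, size = sizes)
  med_long <- matrix(NA_real_, nrow(full), nm)
  for (si in seq_len(ns))
    med_long[full$size == sizes[si], ] <-
      r$median[, (si - 1L) * nm + seq_len(nm), drop = FALSE]
  resc <- rescale_to_max(med_long)
  scores <- numeric(nm)
  for (j in seq_len(nm)) {
    err <- vapply(which(full$size != sizes[1]), function(i) {
      resc[i, j] - resc[full$size == sizes[1] & full$t == full$t[i], j]
    }, numeric(1))
    scores[j] <- .rmse(err)
  }
  names(scores) <- metrics
  cdf <- data.frame(full[rep(seq_len(nrow(full)), nm), ],
                    metric = rep(metrics, each = nrow(full)),
                    median_beta = as.vector(med_long),
                    rescaled = as.vector(resc), row.names = NULL)
  .new_property(id, "quantitative", scores, cdf, seed, n_reps, sum(r$na))
}

.prop_S1 <- function(metrics, n_reps, seed, ...) {
  .prop_sampling("S1", metrics, n_reps, seed, 17L,
                 sizes = c(10000, 9000, 8000, 7000, 6000, 5000, 4000, 3000,
                           2000, 1000, 500, 200, 100, 50, 20, 10),
                 both_sides = TRUE, ...)
}

.prop_S2 <- function(metrics, n_reps, seed, ...) {
  .prop_sampling("S2", metrics, n_reps, seed, 18L,
                 sizes = c(0, 1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000,
                           9000, 9500, 9800, 9900, 9950, 9980, 9990),
                 both_sides = FALSE, ...)
}

.prop_P1 <- function(metrics, n_reps, seed, S = 100, N = 10000,
                     loss_levels = seq(0, 90, 10),
                     t_levels = seq(0, 1, 0.2)) {
  r <- .nested_loss_medians(metrics, n_reps, seed, 19L, loss_levels,
                            t_levels, S, N)
  cells <- r$cells
  resc <- rescale_to_max(r$median)
  scores <- vapply(seq_along(metrics), function(j) {
    err <- vapply(which(cells$loss != 0), function(i) {
      resc[i, j] - resc[cells$loss == 0 & cells$t == cells$t[i], j]
    }, numeric(1))
    .rmse(err)
  }, numeric(1))
  names(scores) <- metrics
  cdf <- data.frame(cells[rep(seq_len(nrow(cells)), length(metrics)), ],
                    metric = rep(metrics, each = nrow(cells)),
                    median_beta = as.vector(r$median),
                    rescaled = as.vector(resc), row.names = NULL)
  .new_property("P1", "personality", scores, cdf, seed, n_reps, r$na)
}

# personality ratios: median beta at an extreme cell over median beta at a
# reference cell (complete turnover unless stated otherwise); numerator and
# denominator pairs are built from the same replicate community
.prop_ratio <- function(id, metrics, n_reps, seed, prop_idx, both_fn) {
  nm <- length(metrics)
  r <- .mc_medians(n_reps, .derive_seed(seed, prop_idx, 1L), function() {
    pr <- both_fn()
    c(beta_pair(pr$num, metrics), beta_pair(pr$den, metrics))
  }, 2L * nm)
  num <- r$median[seq_len(nm)]
  den <- r$median[nm + seq_len(nm)]
  scores <- num / den
  scores[den == 0] <- NA_real_
  names(scores) <- metrics
  cells <- data.frame(metric = metrics, median_numerator = num,
                      median_denominator = den)
  .new_property(id, "personality", scores, cells, seed, n_reps, sum(r$na))
}

.prop_P2 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  .prop_ratio("P2", metrics, n_reps, seed, 20L, function() {
    A <- fisher_assemblage(S, N)
    list(num = nested_loss(A, 90, 0),
         den = .full_turnover_of(A$abundances))
  })
}

.prop_P3 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  .prop_ratio("P3", metrics, n_reps, seed, 21L, function() {
    A <- fisher_assemblage(S, N)
    list(num = decouple_ranks(A, -1),
         den = .full_turnover_of(A$abundances))
  })
}

.prop_P4 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  .prop_ratio("P4", metrics, n_reps, seed, 22L, function() {
    pr <- evenness_pair(S, N, 0.2)
    list(num = pr, den = .full_turnover_of(pr$y))
  })
}

.prop_P5 <- function(metrics, n_reps, seed, S = 100, N = 10000) {
  .prop_ratio("P5", metrics, n_reps, seed, 23L, function() {
    A <- fisher_assemblage(S, N)
    list(num = turnover_one_species(A, "rarest"),
         den = turnover_one_species(A, "dominant"))
  })
}

# ---- public interface ------------------------------------------------------

#' Evaluate one property for a set of metrics
#'
#' Runs the Monte-Carlo simulation design of a single property (conceptual
#' C1-C16, sampling S1-S2, or personality P1-P5) and scores every
#' requested metric: a TRUE/FALSE verdict for qualitative properties, an
#' RMSE for quantitative properties, a non-negative ratio (or RMSE for P1)
#' for personality properties.
#'
#' @param id Property identifier, e.g. `"C6"`, `"S1"`, `"P2"`.
#' @param metrics Registry metric names (default: the 29 scorecard rows).
#' @param n_reps Replicates per simulation cell.
#' @param seed Integer seed; every cell derives an independent substream.
#' @param ... Grid overrides passed to the individual property runner
#'   (e.g. `t_levels`, `S_levels`, `S`, `N`).
#' @return A `"bb_property"` object with fields `scores` (named list or
#'   vector over metrics), `cells` (audit table of cell medians where
#'   applicable), `n_reps`, `seed` and `na_total` (count of replicates on
#'   which some metric was undefined and excluded).
#' @export
evaluate_property <- function(id, metrics = metric_registry()$name,
                              n_reps = 200, seed = 1, ...) {
  id <- toupper(id)
  if (!id %in% .PROPERTY_IDS) stop("unknown property id: ", id)
  fn <- get(paste0(".prop_", id), mode = "function")
  fn(metrics, n_reps, seed, ...)
}

#' Median dissimilarity for one simulation cell
#'
#' Convenience wrapper: the median of a metric over `n_reps` independent
#' replicates of one manipulation applied to freshly drawn Fisher
#' log-series starting assemblages.
#'
#' @param metric Registry metric name.
#' @param kind Manipulation kind: `"turnover"`, `"rank_decoupling"`,
#'   `"evenness"`, `"nested_loss"`.
#' @param parameter The manipulation parameter (t, r, b or number of
#'   species lost).
#' @param t Turnover proportion applied alongside `"nested_loss"`.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param S,N Starting assemblage dimensions.
#' @return The median dissimilarity (NA-excluded).
#' @export
median_beta <- function(metric, kind, parameter, t = 0, n_reps = 200,
                        seed = 1, S = 100, N = 10000) {
  maker <- switch(kind,
    turnover = function(A) apply_turnover(A, parameter),
    rank_decoupling = function(A) decouple_ranks(A, parameter),
    evenness = function(A) evenness_pair(S, N, parameter),
    nested_loss = function(A) nested_loss(A, parameter, t),
    stop("unknown manipulation kind: ", kind))
  r <- .mc_medians(n_reps, .derive_seed(seed, 99L, 1L), function() {
    beta_pair(maker(fisher_assemblage(S, N)), metric)
  }, 1L)
  unname(r$median)
}
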