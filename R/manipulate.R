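# Assemblage manipulations: every perturbation the property harness uses.
#
# All identity manipulations are pure relabelings: novel species inherit the
# abundance of the species they replace, so the abundance multiset is held
# constant and compositional change is isolated from abundance change.

.novel_ids <- function(k, prefix) {
  if (k == 0) return(character(0))
  paste0(prefix, seq_len(k))
}

#' Apply proportional species turnover
#'
#' Builds a pair (A, B) where B carries the same abundance vector as A but a
#' proportion `t` of its species (count `round(t * S)`, ties to even) have
#' been relabeled with novel identities.  Shared species keep identical
#' abundances.
#'
#' @param A An [assemblage].
#' @param t Proportion of species turned over, in \[0, 1\].
#' @param prefix Identifier prefix for the novel species.
#' @return An `"assemblage_pair"`.
#' @export
apply_turnover <- function(A, t, prefix = "nvB") {
  stopifnot(t >= 0, t <= 1)
  k <- round(t * A$S)
  ids_b <- A$species_ids
  if (k > 0) {
    idx <- sample.int(A$S, k)
    ids_b[idx] <- .novel_ids(k, prefix)
  }
  pair_from_assemblages(A, assemblage(ids_b, A$abundances))
}

#' Turn over a single named or extreme species
#'
#' Relabels exactly one species of `A` in the second assemblage: the rarest
#' (lowest abundance, first on ties) or the dominant (highest abundance).
#' Used to probe relative sensitivity to turnover of rare versus common
#' species.
#'
#' @param A An [assemblage].
#' @param which `"rarest"` or `"dominant"`.
#' @return An `"assemblage_pair"`.
#' @export
turnover_one_species <- function(A, which = c("rarest", "dominant")) {
  which <- match.arg(which)
  idx <- if (which == "rarest") which.min(A$abundances) else
    which.max(A$abundances)
  ids_b <- A$species_ids
  ids_b[idx] <- "nv_single"
  pair_from_assemblages(A, assemblage(ids_b, A$abundances))
}

# ---- rank decoupling -------------------------------------------------------

# Noise-scale calibration for rank decoupling: mean Spearman correlation
# between original ranks and ranks of (rank + Gaussian noise), on a sigma
# grid, inverted by interpolation.  Monte-Carlo table cached per richness S;
# built under an isolated RNG state so user streams are unaffected.
.rank_noise_table <- function(S, n_cal = 300L) {
  key <- sprintf("ranknoise_%d", S)
  got <- .bb_cache[[key]]
  if (!is.null(got)) return(got)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(902742L)
  sigma <- c(S / 2^(14:1), S * 2^(0:6))
  rnk <- seq_len(S)
  rho <- vapply(sigma, function(s) {
    mean(vapply(seq_len(n_cal), function(i) {
      stats::cor(rnk, rank(rnk + stats::rnorm(S, 0, s), ties.method = "random"))
    }, numeric(1)))
  }, numeric(1))
  # enforce strictly decreasing rho for interpolation
  for (i in 2:length(rho)) rho[i] <- min(rho[i], rho[i - 1] - 1e-7)
  tab <- list(sigma = sigma, rho = rho)
  .bb_cache[[key]] <- tab
  tab
}

.sigma_for_r <- function(abs_r, S) {
  key <- sprintf("sigma_%d_%.6f", S, abs_r)
  got <- .bb_cache[[key]]
  if (!is.null(got)) return(got)
  tab <- .rank_noise_table(S)
  sig <- if (abs_r >= max(tab$rho)) 0
  else if (abs_r <= min(tab$rho)) Inf
  else exp(stats::approx(tab$rho, log(tab$sigma), xout = abs_r, rule = 2)$y)
  .bb_cache[[key]] <- sig
  sig
}

#' Decouple species abundance ranks at a target correlation
#'
#' Builds a pair (A, B) sharing the species set and the abundance multiset
#' of `A`, with abundances reassigned so that the expected Spearman
#' correlation between the two rank orders equals `r`.  Ranks in B are
#' derived by re-ranking scores `sign(r) * rank_A + eps`, with Gaussian
#' noise variance calibrated by a cached Monte-Carlo lookup so the expected
#' Spearman correlation hits the target; `r = 1` returns the identity,
#' `r = -1` the exact rank reversal, `r = 0` a uniform random permutation.
#'
#' @param A An [assemblage].
#' @param r Target rank correlation in \[-1, 1\].
#' @param noise Optional standard-normal vector of length `S` supplying
#'   the perturbation (scaled internally); sharing it across `r` levels
#'   gives a coupled, smoothly varying family of decouplings for paired
#'   designs.
#' @return An `"assemblage_pair"`; attribute `"ranks"` holds the two rank
#'   vectors.
#' @export
decouple_ranks <- function(A, r, noise = NULL) {
  stopifnot(r >= -1, r <= 1)
  S <- A$S
  ord <- order(A$abundances, decreasing = TRUE)
  rank_a <- integer(S)
  rank_a[ord] <- seq_len(S) # ties broken by species order
  sorted <- A$abundances[ord]
  if (is.null(noise)) noise <- stats::rnorm(S)
  sigma <- if (r == 0) Inf else .sigma_for_r(abs(r), S)
  if (is.infinite(sigma)) {
    rank_b <- integer(S) # pure-noise limit: an unbiased random order
    rank_b[order(noise)] <- seq_len(S)
  } else if (sigma == 0) {
    rank_b <- if (r > 0) rank_a else S + 1L - rank_a
  } else {
    scores <- sign(r) * rank_a + sigma * noise
    rank_b <- integer(S) # scores are continuous: no ties to break
    rank_b[order(scores)] <- seq_len(S)
  }
  ab_b <- sorted[rank_b]
  pair <- new_pair(A$species_ids, A$abundances, ab_b)
  attr(pair, "ranks") <- cbind(rank_a, rank_b)
  pair
}

# ---- evenness --------------------------------------------------------------

#' Build an evenness-contrast pair
#'
#' The first assemblage is maximally uneven: every species is a singleton
#' except the dominant, which holds the remaining `N - S + 1` individuals.
#' The second shares all species identities and the total `N`: individuals
#' surplus to the one-per-species minimum are reallocated multinomially
#' with weights proportional to a Fisher log-series abundance draw (sorted
#' so its ranks align with the first assemblage's) raised to the power
#' `b`.  Large `b` concentrates the weights on the dominant, recovering
#' the uneven start (small evenness difference); small `b` flattens them,
#' redistributing the dominant's individuals across the other species
#' (large evenness difference).  Rank alignment keeps rank decoupling out
#' of a manipulation meant to isolate evenness change.
#'
#' @param S Species count.
#' @param N Total individuals.
#' @param b Redistribution exponent (> 0).
#' @param weights Optional log-series abundance draw to use as the
#'   allocation weights (before sorting and exponentiation); supplying it
#'   lets several `b` levels share one draw in a paired design.
#' @return An `"assemblage_pair"` with attribute `"delta_E"`, the absolute
#'   difference in Pielou evenness between the two assemblages.
#' @export
evenness_pair <- function(S, N, b, weights = NULL) {
  stopifnot(b > 0, S >= 2, N >= S)
  ab1 <- c(N - S + 1, rep(1, S - 1))
  if (is.null(weights)) {
    alpha <- fishers_alpha(S, N)
    weights <- .rlogseries(S, N / (N + alpha))
  }
  w <- sort(weights, decreasing = TRUE)^b
  ab2 <- 1 + as.numeric(stats::rmultinom(1, N - S, prob = w / sum(w)))
  pair <- new_pair(paste0("sp", seq_len(S)), ab1, ab2)
  attr(pair, "delta_E") <- abs(pielou_evenness(ab1) - pielou_evenness(ab2))
  pair
}

# ---- nestedness ------------------------------------------------------------

#' Nested species loss (optionally combined with turnover)
#'
#' Builds a pair (A, B) where B first undergoes proportional turnover `t`
#' (identity relabeling) and then loses `n_lost` randomly chosen species
#' (abundances set to zero), producing a richness difference of `n_lost`.
#'
#' @param A An [assemblage].
#' @param n_lost Number of species removed from the second assemblage
#'   (`0 <= n_lost < S`).
#' @param t Proportion of species turned over before the loss.
#' @return An `"assemblage_pair"`.
#' @export
nested_loss <- function(A, n_lost, t = 0) {
  if (n_lost < 0 || n_lost >= A$S)
    stop("n_lost must be in [0, S): an emptied assemblage is not allowed")
  S <- A$S
  k <- round(t * S)
  ids_b <- A$species_ids
  if (k > 0) ids_b[sample.int(S, k)] <- .novel_ids(k, "nvB")
  ab_b <- A$abundances
  if (n_lost > 0) ab_b[sample.int(S, n_lost)] <- 0
  pair_from_assemblages(A, assemblage(ids_b, ab_b))
}

# ---- structural transforms on pairs ---------------------------------------

#' Replicate every species of a pair
#'
#' Every union species appears `x` times with unchanged abundances (shared
#' species replicate as shared, unique as unique), emulating the pooling of
#' `x` identical subsets.
#'
#' @param pair An `"assemblage_pair"`.
#' @param x Integer replication factor (>= 1).
#' @return An `"assemblage_pair"` with `x` times as many species.
#' @export
replicate_species <- function(pair, x) {
  stopifnot(x >= 1, x == as.integer(x))
  if (x == 1) return(pair)
  u <- paste0(rep(pair$union_species, x), "_r", rep(seq_len(x), each = length(pair$union_species)))
  new_pair(u, rep(pair$x, x), rep(pair$y, x))
}

#' Rescale the abundances of a pair
#'
#' Multiplies the abundances of both assemblages (`which = "both"`,
#' emulating a change in measurement units) or of the first only
#' (`which = "first"`, emulating a difference in total abundance) by a
#' positive factor.  Zeros stay zero, so occupancy is unaffected.
#'
#' @param pair An `"assemblage_pair"`.
#' @param factor Positive multiplier.
#' @param which `"both"` or `"first"`.
#' @return An `"assemblage_pair"`.
#' @export
scale_abundances <- function(pair, factor, which = c("both", "first")) {
  stopifnot(factor > 0)
  which <- match.arg(which)
  x <- pair$x * factor
  y <- if (which == "both") pair$y * factor else pair$y
  new_pair(pair$union_species, x, y)
}

#' Subsample an assemblage without replacement
#'
#' Draws `n` individuals without replacement (a multivariate hypergeometric
#' sample), implemented as a chain of univariate hypergeometric draws.
#' Species sampled to zero are retained with zero abundance so that
#' downstream pairing still aligns identities.
#'
#' @param A An [assemblage] with integer abundances.
#' @param n Sample size, `0 < n <= N`.
#' @return An [assemblage] whose abundances sum exactly to `n`.
#' @export
subsample <- function(A, n) {
  if (n <= 0 || n > A$N) stop("n must be in (0, N]")
  if (n == A$N) return(A)
  ab <- A$abundances
  out <- numeric(length(ab))
  remaining <- A$N
  left <- n
  for (i in seq_along(ab)) {
    if (left == 0) break
    remaining <- remaining - ab[i]
    if (remaining <= 0) { # last urn: take everything still needed
      out[i] <- left
      left <- 0
      break
    }
    k <- stats::rhyper(1, ab[i], remaining, left)
    out[i] <- k
    left <- left - k
  }
  assemblage(A$species_ids, out)
}

# ---- triplets --------------------------------------------------------------

.align_triplet <- function(A, B, C) {
  u <- Reduce(union, list(A$species_ids, B$species_ids, C$species_ids))
  v <- function(Z) { out <- numeric(length(u)); out[match(Z$species_ids, u)] <- Z$abundances; out }
  new_triplet(u, v(A), v(B), v(C))
}

#' Directional turnover along a gradient
#'
#' Builds assemblages A, B, C where B arises from A by proportional
#' turnover `t` and C from B by turning over the same count of species,
#' chosen by weighted sampling without replacement in which species shared
#' between A and B carry weight `g` and species unique to B weight 1.
#' Large `g` makes turnover directional: the species that survived the
#' first step are preferentially replaced in the second.
#'
#' @param A An [assemblage].
#' @param t Per-step turnover proportion (<= 0.5 in the standard design).
#' @param g Gradient strength (>= 1).
#' @return An `"assemblage_triplet"`.
#' @export
gradient_triplet <- function(A, t, g) {
  stopifnot(t >= 0, t <= 1, g >= 1)
  S <- A$S
  k <- round(t * S)
  ids_b <- A$species_ids
  if (k > 0) ids_b[sample.int(S, k)] <- .novel_ids(k, "nvB")
  B <- assemblage(ids_b, A$abundances)
  ids_c <- ids_b
  if (k > 0) {
    w <- ifelse(ids_b %in% A$species_ids, g, 1)
    idx <- sample.int(S, k, prob = w)
    ids_c[idx] <- .novel_ids(k, "nvC")
  }
  C <- assemblage(ids_c, A$abundances)
  .align_triplet(A, B, C)
}

#' Independent draws from a well-mixed species pool
#'
#' Builds assemblages 1, 2, 3 emulating independent, identically
#' distributed samples: assemblage 2 conserves `round(p * S)` randomly
#' chosen species of assemblage 1 (the rest are relabeled with novel
#' identities); assemblage 3 conserves `round(p * S)` randomly chosen
#' species of assemblage 2 in the same way.  Conservation is thus
#' independent at each step, so the expected fraction of species shared
#' between assemblages 1 and 3 is `p^2` -- the hallmark of probabilistic
#' (multiplicative) similarity.  Abundances ride along with the slots they
#' occupy, keeping the abundance multiset constant.
#'
#' @param A An [assemblage].
#' @param p Conservation proportion in \[0, 1\].
#' @return An `"assemblage_triplet"`.
#' @export
iid_triplet <- function(A, p) {
  stopifnot(p >= 0, p <= 1)
  S <- A$S
  k <- round(p * S)
  relabel <- function(ids, prefix) {
    out <- ids
    if (k < S) {
      idx <- sample.int(S, S - k) # the non-conserved slots
      out[idx] <- .novel_ids(S - k, prefix)
    }
    out
  }
  ids2 <- relabel(A$species_ids, "nv2_")
  ids3 <- relabel(ids2, "nv3_")
  .align_triplet(A,
                 assemblage(ids2, A$abundances),
                 assemblage(ids3, A$abundances))
}

# ---- double entries --------------------------------------------------------

#' Append double zeros or double presences to a pair
#'
#' Adds `k` new species carrying abundance (0, 0) (`kind = "zeros"`) or
#' (v, v) with `v` drawn at random from `source` (`kind = "presences"`),
#' the abundance pool of the starting assemblage.
#'
#' @param pair An `"assemblage_pair"`.
#' @param k Number of species to append (0--10 in the standard design).
#' @param kind `"zeros"` or `"presences"`.
#' @param source Abundance pool for double presences; defaults to the
#'   positive abundances already in the pair.
#' @return An `"assemblage_pair"`.
#' @export
add_double_entries <- function(pair, k, kind = c("zeros", "presences"),
                               source = NULL) {
  kind <- match.arg(kind)
  stopifnot(k >= 0)
  if (k == 0) return(pair)
  v <- if (kind == "zeros") rep(0, k) else {
    if (is.null(source)) source <- c(pair$x, pair$y)
    source <- source[source > 0]
    source[sample.int(length(source), k, replace = TRUE)]
  }
  new_pair(c(pair$union_species, .novel_ids(k, paste0("dz", kind))),
           c(pair$x, v), c(pair$y, v))
}
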