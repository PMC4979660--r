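# Assemblage objects and the Fisher log-series sampler.

.bb_cache <- new.env(parent = emptyenv())

#' Construct an assemblage
#'
#' An assemblage is a set of uniquely identified species with non-negative
#' integer-like abundances.  Richness `S` counts strictly positive
#' abundances and `N` is the abundance total.
#'
#' @param species_ids Character vector of unique species identifiers.
#' @param abundances Numeric vector of non-negative abundances, aligned to
#'   `species_ids`.
#' @return An object of class `"assemblage"` with fields `species_ids`,
#'   `abundances`, `S` and `N`.
#' @export
assemblage <- function(species_ids, abundances) {
  species_ids <- as.character(species_ids)
  abundances <- as.numeric(abundances)
  if (length(species_ids) != length(abundances))
    stop("species_ids and abundances must have equal length")
  if (anyDuplicated(species_ids))
    stop("species_ids must be unique within an assemblage")
  if (any(abundances < 0) || anyNA(abundances))
    stop("abundances must be non-negative")
  structure(
    list(species_ids = species_ids, abundances = abundances,
         S = sum(abundances > 0), N = sum(abundances)),
    class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat("Assemblage:", x$S, "species,", format(x$N, big.mark = ","),
      "individuals\n")
  invisible(x)
}

#' Fisher's alpha from richness and abundance
#'
#' Solves `S = alpha * log(1 + N / alpha)` for alpha, the maximum-likelihood
#' estimate of Fisher's log-series parameter given richness `S` and total
#' abundance `N`.
#'
#' @param S Species richness (>= 1).
#' @param N Total number of individuals (>= S).
#' @return Fisher's alpha (positive scalar).
#' @export
fishers_alpha <- function(S, N) {
  stopifnot(S >= 1, N >= S)
  if (S == N) return(Inf) # all singletons: degenerate limit
  f <- function(a) a * log1p(N / a) - S
  stats::uniroot(f, lower = 1e-8, upper = S * 1e6, tol = 1e-12)$root
}

# Cumulative distribution of the logarithmic series with parameter x,
# truncated where the tail mass drops below ~1e-13.  Cached per x.
.logseries_cdf <- function(x) {
  key <- sprintf("logcdf_%.15g", x)
  got <- .bb_cache[[key]]
  if (!is.null(got)) return(got)
  # support cap: x^n/n < x^n, need x^nmax ~ 1e-13
  nmax <- max(50L, ceiling(log(1e-13) / log(x)))
  n <- seq_len(nmax)
  p <- x^n / n
  cdf <- cumsum(p) / sum(p)
  .bb_cache[[key]] <- cdf
  cdf
}

# Draw k abundances i.i.d. from the logarithmic series distribution.
.rlogseries <- function(k, x) {
  cdf <- .logseries_cdf(x)
  findInterval(stats::runif(k), cdf, left.open = TRUE) + 1L
}

#' Draw a Fisher log-series assemblage
#'
#' Generates a hypothetical species assemblage whose abundance structure
#' follows Fisher's log-series.  Given target expectations
#' (`S_target`, `N_target`), alpha is solved from
#' `S = alpha * log(1 + N / alpha)` and each of the `S_target` species
#' receives an abundance drawn i.i.d. from the logarithmic distribution
#' with parameter `x = N / (N + alpha)`, so that realized richness is
#' exactly `S_target` and total abundance has expectation `N_target`.
#'
#' @param S_target Expected (and realized) species richness.
#' @param N_target Expected number of individuals.
#' @param prefix Prefix for generated species identifiers.
#' @return An [assemblage] with `S_target` species, each abundance a
#'   positive integer.
#' @export
fisher_assemblage <- function(S_target, N_target, prefix = "sp") {
  if (S_target < 1) stop("S_target must be at least 1")
  if (S_target > N_target)
    stop("infeasible: S_target exceeds N_target (fewer individuals than species)")
  alpha <- fishers_alpha(S_target, N_target)
  if (!is.finite(alpha)) { # S == N: all species singletons
    ab <- rep(1L, S_target)
  } else {
    x <- N_target / (N_target + alpha)
    ab <- .rlogseries(S_target, x)
  }
  assemblage(paste0(prefix, seq_len(S_target)), ab)
}

#' Pielou evenness
#'
#' Shannon entropy of relative abundances divided by `log(S)`; 1 for a
#' perfectly even assemblage, near 0 for extreme dominance.  Returns `NA`
#' for assemblages with a single species.
#'
#' @param abundances Non-negative abundance vector.
#' @return Evenness in \[0, 1\].
#' @export
pielou_evenness <- function(abundances) {
  a <- abundances[abundances > 0]
  if (length(a) < 2) return(NA_real_)
  p <- a / sum(a)
  -sum(p * log(p)) / log(length(a))
}

# ---- aligned pairs and triplets -------------------------------------------

#' Align assemblages over their species union
#'
#' Builds the aligned abundance-vector representation consumed by every
#' metric: one column per assemblage over the ordered union of species.
#'
#' @param A,B Assemblages.
#' @return An object of class `"assemblage_pair"` with fields
#'   `union_species`, `x` and `y`.
#' @export
pair_from_assemblages <- function(A, B) {
  u <- union(A$species_ids, B$species_ids)
  x <- y <- numeric(length(u))
  x[match(A$species_ids, u)] <- A$abundances
  y[match(B$species_ids, u)] <- B$abundances
  keep <- x > 0 | y > 0 # double zeros only enter via add_double_entries
  new_pair(u[keep], x[keep], y[keep])
}

new_pair <- function(union_species, x, y) {
  structure(list(union_species = union_species, x = x, y = y),
            class = "assemblage_pair")
}

#' Construct an assemblage pair from abundance vectors
#'
#' @param x,y Non-negative abundance vectors of equal length, aligned to a
#'   common species list.
#' @param species Optional species identifiers (defaults to `s1, s2, ...`).
#' @return An `"assemblage_pair"`.
#' @export
assemblage_pair <- function(x, y, species = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (is.null(species)) species <- paste0("s", seq_along(x))
  new_pair(as.character(species), as.numeric(x), as.numeric(y))
}

#' @export
print.assemblage_pair <- function(x, ...) {
  cat("Assemblage pair over", length(x$union_species), "species;",
      "shared:", sum(x$x > 0 & x$y > 0), "\n")
  invisible(x)
}

new_triplet <- function(union_species, x, y, z) {
  structure(list(union_species = union_species, x = x, y = y, z = z),
            class = "assemblage_triplet")
}

#' Extract one pair from a triplet
#'
#' @param trip An `"assemblage_triplet"`.
#' @param which One of `"AB"`, `"BC"`, `"AC"`.
#' @return An `"assemblage_pair"` aligned over the triplet's species union.
#' @export
triplet_pair <- function(trip, which = c("AB", "BC", "AC")) {
  which <- match.arg(which)
  sel <- switch(which, AB = c("x", "y"), BC = c("y", "z"), AC = c("x", "z"))
  a <- trip[[sel[1]]]; b <- trip[[sel[2]]]
  keep <- a > 0 | b > 0
  new_pair(trip$union_species[keep], a[keep], b[keep])
}

# ---- text serialization ----------------------------------------------------

#' Read / write community matrices and assemblages as delimited text
#'
#' A community matrix has one row per assemblage and one column per species
#' (non-negative counts).  A single assemblage serializes as two columns,
#' `species_id` and `abundance`.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return `read_community` returns a numeric matrix with row and column
#'   names; `read_assemblage` returns an [assemblage].
#' @export
read_community <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("community matrix must be non-negative")
  m
}

#' @param comm Community matrix (assemblages in rows, species in columns).
#' @rdname read_community
#' @export
write_community <- function(comm, file, sep = ",") {
  utils::write.table(cbind(assemblage = rownames(comm), as.data.frame(comm)),
                     file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @param A An [assemblage].
#' @rdname read_community
#' @export
write_assemblage <- function(A, file, sep = ",") {
  utils::write.table(
    data.frame(species_id = A$species_ids, abundance = A$abundances),
    file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Convert a pair or triplet to a community matrix
#'
#' Rows are assemblages, columns the union species: the sites-by-species
#' layout accepted by [beta_matrix] and [write_community].
#'
#' @param x An `"assemblage_pair"` or `"assemblage_triplet"`.
#' @return A numeric matrix with one row per assemblage.
#' @export
as_community <- function(x) {
  rows <- if (inherits(x, "assemblage_triplet")) c("x", "y", "z") else
    c("x", "y")
  m <- do.call(rbind, lapply(rows, function(f) x[[f]]))
  dimnames(m) <- list(paste0("A", seq_along(rows)), x$union_species)
  m
}

#' @rdname read_community
#' @export
read_assemblage <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         colClasses = c("character", "numeric"))
  assemblage(d[[1]], d[[2]])
}
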