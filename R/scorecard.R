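# Scorecard aggregation, Pareto dominance, and PCA of quantitative scores.

.SC_QUAL_COUNTED <- c("C3", "C5", "C7", "C8", "C9", "C10", "C12", "C13")
.SC_QUANT <- c("C1", "C2", "C3", "C14", "C15", "C16", "S1", "S2")
.SC_DESIRABLE <- c(paste0("C", 1:16), "S1", "S2")
.SC_PCA_DEFAULT <- c("C1", "C2", "C14", "C15", "C16", "S1", "S2",
                     "P1", "P2", "P3", "P4", "P5")

.score_of <- function(prop, metric) {
  s <- prop$scores[[metric]]
  if (is.null(s)) NA else s
}

#' Build the scorecard from a full set of property results
#'
#' Aggregates per-metric property scores into the scorecard table:
#' qualitative verdicts, quantitative RMSE scores, personality scores,
#' the number of TRUE/FALSE verdicts, and the mean of quantitative scores.
#' Following the table convention, the universally satisfied properties
#' C4, C6 and C11 are reported but excluded from the TRUE/FALSE counts,
#' while the probabilistic-similarity property counts as a verdict: TRUE
#' when the metric has a similarity complement (its departure is then also
#' reported as an RMSE), FALSE when it does not.  Rows are ordered by
#' number of TRUEs (descending) then mean quantitative score (ascending);
#' ties keep registry order.
#'
#' @param props Named list of `"bb_property"` results covering C1-C16,
#'   S1, S2 and P1-P5 (as produced by [run_benchmark] or
#'   [evaluate_property]).
#' @param metrics Metric names (rows); default: every metric scored in
#'   `props$C1`.
#' @param digits Precision at which dominance comparisons are made; see
#'   [pareto_dominated].
#' @return A data frame of class `"bb_scorecard"`, one row per metric,
#'   with a `pareto_dominated` flag (see [pareto_dominated]).
#' @export
build_scorecard <- function(props, metrics = NULL, digits = 4) {
  need <- c(.SC_DESIRABLE, paste0("P", 1:5))
  missing <- setdiff(need, names(props))
  if (length(missing))
    stop("missing property results: ", paste(missing, collapse = ", "))
  if (is.null(metrics)) metrics <- names(props$C1$scores)
  qual_ids <- c("C4", "C5", "C6", "C7", "C8", "C9", "C10", "C11", "C12", "C13")
  sc <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  sc$display <- .DISPLAY_NAMES[metrics]
  for (id in c("C1", "C2")) sc[[id]] <- vapply(metrics, function(m)
    as.numeric(.score_of(props[[id]], m)), numeric(1))
  sc$C3 <- vapply(metrics, function(m) {
    s <- .score_of(props$C3, m)
    if (isFALSE(s)) NA_real_ else as.numeric(s)
  }, numeric(1))
  sc$C3_pass <- vapply(metrics, function(m) !isFALSE(.score_of(props$C3, m)),
                       logical(1))
  for (id in qual_ids) sc[[id]] <- vapply(metrics, function(m)
    isTRUE(.score_of(props[[id]], m)), logical(1))
  for (id in c("C14", "C15", "C16", "S1", "S2", paste0("P", 1:5)))
    sc[[id]] <- vapply(metrics, function(m)
      as.numeric(.score_of(props[[id]], m)), numeric(1))
  counted <- cbind(sc$C3_pass, as.matrix(sc[, c("C5", "C7", "C8", "C9",
                                                "C10", "C12", "C13")]))
  sc$n_true <- rowSums(counted)
  sc$n_false <- ncol(counted) - sc$n_true
  quant <- as.matrix(sc[, .SC_QUANT])
  sc$mean_quantitative <- rowMeans(quant, na.rm = TRUE)
  sc$pareto_dominated <- pareto_dominated(sc, digits = digits)$dominated
  ord <- order(-sc$n_true, sc$mean_quantitative)
  sc <- sc[ord, ]
  rownames(sc) <- NULL
  class(sc) <- c("bb_scorecard", "data.frame")
  sc
}

# comparable matrix for dominance: one column per desirable property,
# larger = better.  Qualitative verdicts map to 1/0; quantitative scores
# are negated (lower RMSE is better); a missing similarity complement
# makes the probabilistic-similarity score -Inf (worse than any RMSE).
.dominance_matrix <- function(sc) {
  cols <- lapply(.SC_DESIRABLE, function(id) {
    if (id == "C3") {
      v <- -sc$C3
      v[!sc$C3_pass] <- -Inf
      v
    } else if (id %in% c("C4", "C5", "C6", "C7", "C8", "C9", "C10",
                         "C11", "C12", "C13")) {
      as.numeric(sc[[id]])
    } else {
      -sc[[id]]
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- .SC_DESIRABLE
  rownames(m) <- sc$metric
  m
}

#' Pareto dominance over the desirable properties
#'
#' A metric is Pareto-dominated when some other metric is at least as good
#' on every desirable property (conceptual C1-C16 and sampling S1-S2;
#' personality is excluded): TRUE beats FALSE on qualitative verdicts and
#' a lower score is better on quantitative ones.  Weak dominance is used,
#' except that a pair of metrics identical on every property is mutually
#' tied, not dominated; such ties are reported separately.
#'
#' @param sc A `"bb_scorecard"` (or the data frame being built).
#' @param digits Precision (decimal places) at which quantitative scores
#'   are compared; the default, 4, treats differences below the reported
#'   precision -- which at finite replication are Monte-Carlo noise, not
#'   evidence that one metric outperforms another -- as ties.  Use
#'   `digits = NULL` to compare raw scores.
#' @return A list: `dominated` (logical, aligned to `sc` rows),
#'   `dominated_by` (list of dominator names per metric) and `ties`
#'   (character matrix of exactly-tied pairs, possibly empty).
#' @export
pareto_dominated <- function(sc, digits = 4) {
  m <- .dominance_matrix(sc)
  if (!is.null(digits)) m <- round(m, digits)
  n <- nrow(m)
  dominated <- logical(n)
  dominated_by <- vector("list", n)
  ties <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      geq <- all(m[j, ] >= m[i, ])
      identical_all <- geq && all(m[j, ] <= m[i, ])
      if (identical_all) {
        if (j > i) ties[[length(ties) + 1L]] <- c(rownames(m)[i], rownames(m)[j])
        next
      }
      if (geq) {
        dominated[i] <- TRUE
        dominated_by[[i]] <- c(dominated_by[[i]], rownames(m)[j])
      }
    }
  }
  list(dominated = dominated,
       dominated_by = stats::setNames(dominated_by, rownames(m)),
       ties = if (length(ties)) do.call(rbind, ties) else
         matrix(character(0), 0, 2))
}

#' PCA of the quantitative score matrix
#'
#' Principal component analysis of the metric-by-score matrix for the
#' quantitatively measured properties (default: C1-C2, C14-C16, S1-S2 and
#' P1-P5), on standardized columns (centred, unit variance); constant
#' columns are dropped with a warning.
#'
#' @param sc A `"bb_scorecard"`.
#' @param properties Quantitative property columns to use.
#' @param metrics Optional subset of metric rows (default: all rows).
#' @return A list with `scores` (metric coordinates), `loadings`,
#'   `variance_explained` (fractions summing to 1) and the fitted
#'   `prcomp` object.
#' @export
pca_scores <- function(sc, properties = .SC_PCA_DEFAULT, metrics = NULL) {
  rows <- if (is.null(metrics)) seq_len(nrow(sc)) else
    match(metrics, sc$metric)
  m <- as.matrix(sc[rows, properties, drop = FALSE])
  rownames(m) <- sc$metric[rows]
  keep <- apply(m, 2, function(col) stats::sd(col, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning("dropping constant score column(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  if (anyNA(m)) stop("PCA input contains missing scores")
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation, variance_explained = ve,
       prcomp = fit)
}

#' @export
print.bb_scorecard <- function(x, digits = 4, ...) {
  if (is.null(x$display) || is.null(x$n_true)) { # subsetted: plain frame
    return(print.data.frame(x, ...))
  }
  show <- data.frame(metric = x$display, n_true = x$n_true,
                     n_false = x$n_false,
                     mean_quant = round(x$mean_quantitative, digits),
                     dominated = ifelse(x$pareto_dominated, "*", ""))
  print(show, row.names = FALSE)
  invisible(x)
}
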