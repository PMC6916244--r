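# Unsupervised structure and static-threshold screening of AE parameters.

#' PCA of the AE waveform parameters
#'
#' Standardizes each column to unit variance (the parameters span several
#' orders of magnitude across units) and decomposes. Constant columns are
#' dropped with a warning.
#'
#' @param features Numeric matrix or data frame (e.g. the 18 waveform
#'   parameters, one row per signal).
#' @return Object of class `ae_pca`: `loadings` (orthonormal columns),
#'   `explained` (variance fractions summing to 1), `sdev`, `dropped`.
#' @export
pca_summary <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  structure(list(loadings = p$rotation,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 sdev = p$sdev, dropped = dropped),
            class = "ae_pca")
}

#' @export
print.ae_pca <- function(x, ...) {
  k <- min(5L, length(x$explained))
  cat("PCA of AE waveform parameters\n")
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Correlation matrix of AE waveform parameters
#'
#' Pearson correlations; constant columns yield `NA` entries and a warning.
#'
#' @param features Numeric matrix or data frame.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  suppressWarnings(r <- cor(x))
  const <- apply(x, 2, sd) == 0
  if (any(const))
    warning("constant column(s) give undefined correlations: ",
            paste(colnames(x)[const], collapse = ", "))
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}

#' Upper-level histogram threshold for one window
#'
#' Finds the parameter value such that exactly the window's microCT embolism
#' count of signals lies strictly above it; ties are broken by retaining the
#' earlier timestamps.
#'
#' @param values Parameter values of the window's signals.
#' @param count The window's microCT embolism count.
#' @param times Optional timestamps for tie-breaking (defaults to input order).
#' @return List: `threshold`, `retained` (indices into `values`, earliest
#'   first among ties).
#' @export
histogram_threshold <- function(values, count, times = NULL) {
  n <- length(values)
  if (count > n)
    stop("embolism count (", count, ") exceeds window size (", n, ")",
         call. = FALSE)
  if (is.null(times)) times <- seq_len(n)
  ord <- order(-values, times)
  retained <- sort(ord[seq_len(count)])
  threshold <- if (count == 0L) max(values)
  else if (count == n) -Inf
  else max(values[-ord[seq_len(count)]])
  list(threshold = threshold, retained = retained)
}

## Shared ROC engine over per-signal values with window-count supervision.
## Per-signal truth is unavailable, so true positives are counted capped:
## within window d at threshold t, TP_d = min(#values > t, count_d) and the
## excess is false positive. The uncapped variant treats every retained
## signal of an event window as a true positive.
roc_from_values <- function(values, assignment, counts, cap = TRUE) {
  ok <- !is.na(assignment)
  values <- values[ok]; assignment <- assignment[ok]
  if (all(counts == 0)) stop("no positives: all window counts are zero",
                             call. = FALSE)
  thresholds <- c(sort(unique(values), decreasing = TRUE), -Inf)
  nt <- length(thresholds)
  tp <- numeric(nt); fp <- numeric(nt)
  pos_total <- 0; neg_total <- 0
  for (d in seq_along(counts)) {
    v <- sort(values[assignment == d])
    m <- length(v)
    if (cap) { pos_total <- pos_total + counts[d]; neg_total <- neg_total + m - counts[d] }
    else if (counts[d] > 0) pos_total <- pos_total + m
    else neg_total <- neg_total + m
    if (m == 0L) next
    retained <- m - findInterval(thresholds, v)  # values strictly > t
    if (cap) {
      tpd <- pmin(retained, counts[d])
      tp <- tp + tpd
      fp <- fp + retained - tpd
    } else if (counts[d] > 0) tp <- tp + retained
    else fp <- fp + retained
  }
  structure(list(curve = data.frame(threshold = thresholds,
                                    tpr = tp / pos_total,
                                    fpr = fp / max(neg_total, 1)),
                 positives_total = pos_total, negatives_total = neg_total,
                 capped = cap),
            class = "roc_curve")
}

#' ROC curve for a single AE parameter under count supervision
#'
#' Sweeps thresholds from the global maximum of the parameter downwards
#' (first point (0,0)) to below the minimum (last point (1,1)). True and
#' false positive rates are computed against the per-window microCT counts:
#' within a window, at most its count of retained signals can be true
#' positives (capped counting); the remainder are false positives.
#'
#' @param windows An `ae_windows` object from [link_windows()].
#' @param parameter Column name of the parameter to threshold.
#' @param cap Use capped within-window counting (default) or label every
#'   retained signal of an event window a true positive.
#' @return Object of class `roc_curve` with elements `curve` (`threshold`,
#'   `tpr`, `fpr`), `positives_total`, `negatives_total`.
#' @export
roc_parameter <- function(windows, parameter, cap = TRUE) {
  stopifnot(inherits(windows, "ae_windows"))
  v <- windows$signals[[parameter]]
  if (is.null(v)) stop("unknown parameter: ", parameter, call. = FALSE)
  roc_from_values(v, windows$assignment, windows$windows$embolism_count, cap)
}

#' Area under a ROC curve (trapezoid rule)
#' @param roc A `roc_curve` object.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  cv <- roc$curve
  o <- order(cv$fpr, cv$tpr)
  sum(diff(cv$fpr[o]) * (utils::head(cv$tpr[o], -1) + utils::tail(cv$tpr[o], -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, %d positives / %d negatives, AUC %.3f (%s counting)\n",
              nrow(x$curve), x$positives_total, x$negatives_total, roc_auc(x),
              if (x$capped) "capped" else "uncapped"))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
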