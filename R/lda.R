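# Count-weighted linear discriminant analysis: a generative two-class model
# (class means mu0/mu1, shared covariance Sigma, prior) fitted from
# window-level embolism counts only - per-signal labels are never observed.

## Per-window sufficient statistics from a feature matrix and an assignment.
window_stats <- function(features, assignment, counts) {
  p <- ncol(features)
  W <- length(counts)
  m <- tabulate(assignment[!is.na(assignment)], W)
  if (any(counts > m))
    stop("window ", which(counts > m)[1], " has count ", counts[which(counts > m)[1]],
         " exceeding its size ", m[which(counts > m)[1]], call. = FALSE)
  sum_x <- matrix(0, W, p, dimnames = list(NULL, colnames(features)))
  sxx <- vector("list", W)
  for (d in seq_len(W)) {
    xd <- features[!is.na(assignment) & assignment == d, , drop = FALSE]
    sum_x[d, ] <- colSums(xd)
    sxx[[d]] <- crossprod(xd)
  }
  list(m = m, n1 = counts, n0 = m - counts, sum_x = sum_x, sxx = sxx, p = p)
}

## Class means from window summaries.
estimate_means <- function(ws, method) {
  use <- ws$m > 0
  xbar <- ws$sum_x[use, , drop = FALSE] / ws$m[use]
  n1 <- ws$n1[use]; n0 <- ws$n0[use]; m <- ws$m[use]
  if (method == "weighted") {
    ## the count-weighted average of window mean vectors
    mu1 <- colSums(xbar * n1) / sum(n1)
    mu0 <- colSums(xbar * n0) / sum(n0)
  } else {
    ## moment-corrected: E[xbar_d] = mu0 + p_d (mu1 - mu0); weighted least
    ## squares of window means on the count proportion p_d, weights m_d
    pd <- n1 / m
    X <- cbind(1, pd)
    XtWX <- crossprod(X * m, X)
    beta <- solve(XtWX, crossprod(X * m, xbar))
    mu0 <- beta[1, ]
    mu1 <- beta[1, ] + beta[2, ]
  }
  list(mu0 = mu0, mu1 = mu1)
}

## Pooled covariance; each window centred at `centers[d, ]`.
estimate_sigma <- function(ws, centers) {
  use <- which(ws$m > 0)
  p <- ws$p
  S <- matrix(0, p, p)
  for (d in use) {
    cd <- centers[d, ]
    S <- S + ws$sxx[[d]] - outer(ws$sum_x[d, ], cd) - outer(cd, ws$sum_x[d, ]) +
      ws$m[d] * outer(cd, cd)
  }
  S / sum(ws$m)
}

## Relative ridge until the covariance factorizes.
regularize_sigma <- function(sigma, ridge = 1e-8) {
  p <- ncol(sigma)
  eps <- ridge * sum(diag(sigma)) / p
  for (i in 0:40) {
    ok <- !inherits(try(chol(sigma), silent = TRUE), "try-error") &&
      rcond(sigma) > 1e-14
    if (ok) return(sigma)
    sigma <- sigma + diag(eps * 2^i, p)
  }
  stop("covariance is singular even after regularization", call. = FALSE)
}

## Fit from window summaries only; shared by count_lda() and the LOO folds.
fit_from_ws <- function(ws, method, cov_center, ridge, prior, feature_names) {
  mu <- estimate_means(ws, method)
  centers <- if (cov_center == "model")
    (outer(ws$n1, mu$mu1) + outer(ws$n0, mu$mu0)) / pmax(ws$m, 1L)
  else ws$sum_x / pmax(ws$m, 1L)
  sigma <- regularize_sigma(estimate_sigma(ws, centers), ridge)
  prior1 <- if (is.null(prior)) sum(ws$n1) / sum(ws$m) else prior
  if (prior1 <= 0 || prior1 >= 1)
    stop("prior must lie strictly inside (0, 1)", call. = FALSE)
  a <- solve(sigma, mu$mu1 - mu$mu0)           # discriminant direction
  b <- -0.5 * sum((mu$mu1 + mu$mu0) * a) + qlogis(prior1)
  names(a) <- feature_names
  structure(list(mu0 = setNames(mu$mu0, feature_names),
                 mu1 = setNames(mu$mu1, feature_names),
                 sigma = sigma, prior1 = prior1,
                 coefficients = c(`(Intercept)` = b, a),
                 features = feature_names, method = method,
                 cov_center = cov_center,
                 n_windows = length(ws$m), n_signals = sum(ws$m),
                 n_events = sum(ws$n1)),
            class = "count_lda")
}

## Drop one window from a summary set.
drop_window_ws <- function(ws, d) {
  list(m = ws$m[-d], n1 = ws$n1[-d], n0 = ws$n0[-d],
       sum_x = ws$sum_x[-d, , drop = FALSE], sxx = ws$sxx[-d], p = ws$p)
}

#' Fit a linear discriminant model from window-level embolism counts
#'
#' Fits the generative two-class model in which non-embolism features are
#' distributed `N(mu0, Sigma)` and embolism features `N(mu1, Sigma)`, using
#' only per-window event counts as supervision. With `method = "weighted"`
#' (the default) the class means are count-weighted averages of the window
#' mean feature vectors: `mu1 = sum(n1_d xbar_d) / sum(n1_d)` and
#' `mu0 = sum(n0_d xbar_d) / sum(n0_d)` with `n0_d` the complement count
#' (window size minus events). The shared covariance pools, over all windows,
#' the scatter of each signal about its window's model-implied mixture mean
#' `(n1_d mu1 + n0_d mu0) / m_d` (so that on pure windows the fit coincides
#' exactly with supervised LDA); `cov_center = "window"` instead centres each
#' window at its own mean. The class prior is the global count ratio.
#'
#' The weighted estimator is attenuated when windows mix classes (each window
#' mean blends both class means); `method = "moment"` removes that bias by
#' solving the two-point mixture moment equations (weighted regression of
#' window means on the window count proportion).
#'
#' @param x An `ae_windows` object, or a numeric feature matrix.
#' @param ... Passed on to methods.
#' @return An object of class `count_lda`; see Details.
#' @seealso [predict.count_lda()], [predict_window_count()],
#'   [loo_crossvalidate()], [roc_lda()]
#' @export
count_lda <- function(x, ...) UseMethod("count_lda")

#' @rdname count_lda
#' @export
count_lda.ae_windows <- function(x, ...) {
  fit <- count_lda.default(x$features, x$assignment, x$windows$embolism_count, ...)
  fit$call <- match.call()
  fit
}

#' @rdname count_lda
#' @param assignment Window index per row of `x` (`NA` rows are ignored).
#' @param counts Per-window embolism counts.
#' @param prior Class-1 prior probability; default the global count ratio.
#' @param method `"weighted"` (faithful count-weighted averages) or
#'   `"moment"` (bias-corrected mixture regression).
#' @param cov_center `"model"` (mixture-mean centring; default) or
#'   `"window"` (window-mean centring).
#' @param ridge Relative ridge added to a near-singular covariance diagonal.
#' @export
count_lda.default <- function(x, assignment, counts,
                              prior = NULL,
                              method = c("weighted", "moment"),
                              cov_center = c("model", "window"),
                              ridge = 1e-8, ...) {
  method <- match.arg(method)
  cov_center <- match.arg(cov_center)
  features <- as.matrix(x)
  counts <- as.integer(counts)
  if (all(counts == 0L)) stop("all window counts are zero: no positives to learn from",
                              call. = FALSE)
  if (length(counts) < 2L) stop("need at least 2 windows", call. = FALSE)
  ws <- window_stats(features, assignment, counts)
  if (all(ws$n0 == 0L)) stop("every signal is an event: no background to learn from",
                             call. = FALSE)
  fit <- fit_from_ws(ws, method, cov_center, ridge, prior, colnames(features))
  fit$call <- match.call()
  ## training-window fitted counts for residual diagnostics
  post <- predict(fit, features, type = "posterior")
  fitted <- vapply(seq_along(counts), function(d)
    sum(post[!is.na(assignment) & assignment == d]), numeric(1))
  fit$fitted.values <- fitted
  fit$observed <- counts
  fit
}

#' Posterior probability of embolism for AE signals
#'
#' Evaluates `P(Y = 1 | x)` by Bayes' rule with the two fitted normal
#' likelihoods, computed through the log-density difference (the linear
#' discriminant score) for numerical stability.
#'
#' @param object A fitted `count_lda` model.
#' @param newdata Feature matrix, data frame with the feature columns, or a
#'   single feature vector.
#' @param type `"posterior"` (default), `"logodds"`, or `"class"` (arg-max
#'   label, 0/1).
#' @param ... Unused.
#' @return Numeric vector (or integer vector for `type = "class"`).
#' @export
predict.count_lda <- function(object, newdata, type = c("posterior", "logodds", "class"),
                              ...) {
  type <- match.arg(type)
  x <- newdata
  if (is.data.frame(x)) x <- extract_features(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$mu0))
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object$mu0), call. = FALSE)
  lo <- drop(x %*% object$coefficients[-1] + object$coefficients[1])
  switch(type,
         logodds = lo,
         posterior = plogis(lo),
         class = as.integer(lo > 0))
}

#' @rdname predict.count_lda
#' @param model A fitted `count_lda` model.
#' @param x Feature vector or matrix.
#' @export
posterior_embolism <- function(model, x) predict(model, x, type = "posterior")

#' Expected embolism count of a window
#'
#' Sums the per-signal embolism posteriors of a window's members ("cumulated
#' probabilities"); always between 0 and the window size.
#'
#' @param model A fitted `count_lda` model.
#' @param features Feature matrix (or data frame) of the window's signals;
#'   zero rows give 0.
#' @return Expected number of embolism events in the window.
#' @export
predict_window_count <- function(model, features) {
  if (is.data.frame(features)) features <- extract_features(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (nrow(features) == 0L) return(0)
  sum(predict(model, features, type = "posterior"))
}

#' @export
print.count_lda <- function(x, ...) {
  cat("Count-weighted linear discriminant model\n")
  cat(sprintf("  %d signals in %d windows, %d microCT events (prior %.4f)\n",
              x$n_signals, x$n_windows, x$n_events, x$prior1))
  cat(sprintf("  estimator: %s means, %s-centred covariance\n",
              x$method, x$cov_center))
  mm <- rbind(mu0 = x$mu0, mu1 = x$mu1)
  colnames(mm) <- x$features
  print(round(mm, 3))
  invisible(x)
}

#' @export
summary.count_lda <- function(object, ...) {
  structure(list(model = object,
                 mahalanobis = sqrt(sum((object$mu1 - object$mu0) *
                                          solve(object$sigma, object$mu1 - object$mu0))),
                 predicted_total = sum(object$fitted.values),
                 observed_total = sum(object$observed)),
            class = "summary.count_lda")
}

#' @export
print.summary.count_lda <- function(x, ...) {
  print(x$model)
  cat(sprintf("  class separation (Mahalanobis): %.2f\n", x$mahalanobis))
  cat(sprintf("  predicted events over training windows: %.1f (observed %d)\n",
              x$predicted_total, x$observed_total))
  invisible(x)
}

#' @export
coef.count_lda <- function(object, ...) object$coefficients

#' @export
fitted.count_lda <- function(object, ...) object$fitted.values

#' @export
residuals.count_lda <- function(object, ...) object$observed - object$fitted.values

#' Simulate feature vectors from the fitted generative model
#'
#' Draws labels from the fitted prior and features from the corresponding
#' class normal - the generative counterpart of classification.
#'
#' @param object A fitted `count_lda` model.
#' @param nsim Number of signals to draw.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame of features plus a `label` column.
#' @export
simulate.count_lda <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lab <- as.integer(runif(nsim) < object$prior1)
  x <- matrix(NA_real_, nsim, length(object$mu0),
              dimnames = list(NULL, object$features))
  if (any(lab == 1L))
    x[lab == 1L, ] <- MASS::mvrnorm(sum(lab), object$mu1, object$sigma)
  if (any(lab == 0L))
    x[lab == 0L, ] <- MASS::mvrnorm(sum(1 - lab), object$mu0, object$sigma)
  data.frame(x, label = lab)
}

#' @export
plot.count_lda <- function(x, ...) {
  a <- x$coefficients[-1]
  s2 <- drop(t(a) %*% x$sigma %*% a)
  m0 <- sum(a * x$mu0); m1 <- sum(a * x$mu1)
  g <- seq(min(m0, m1) - 4 * sqrt(s2), max(m0, m1) + 4 * sqrt(s2), length.out = 400)
  d0 <- dnorm(g, m0, sqrt(s2)); d1 <- dnorm(g, m1, sqrt(s2))
  plot(g, d0, type = "l", xlab = "discriminant score", ylab = "density",
       main = "Fitted class-conditional score densities", ...)
  lines(g, d1, col = 2)
  legend("topright", c("background", "embolism"), col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Leave-one-window-out cross-validation
#'
#' For each window, refits the model on all remaining windows and predicts
#' the held-out window's expected event count (sum of posteriors). Training
#' folds left without any positive count fall back to the full-data model and
#' are flagged with a warning.
#'
#' @param windows An `ae_windows` object.
#' @param ... Passed to [count_lda()] (e.g. `method`, `cov_center`).
#' @return Object of class `count_lda_cv`: data frame `window`, `kind`,
#'   `size`, `observed`, `predicted`, `flagged`, with attributes
#'   `total_observed` and `total_predicted`.
#' @export
loo_crossvalidate <- function(windows, ...) {
  stopifnot(inherits(windows, "ae_windows"))
  counts <- windows$windows$embolism_count
  W <- length(counts)
  if (W < 3L) stop("need at least 3 windows", call. = FALSE)
  assignment <- windows$assignment
  features <- windows$features
  full <- count_lda(windows, ...)
  opts <- list(...)
  method <- if (is.null(opts$method)) "weighted" else match.arg(opts$method, c("weighted", "moment"))
  cov_center <- if (is.null(opts$cov_center)) "model" else match.arg(opts$cov_center, c("model", "window"))
  ridge <- if (is.null(opts$ridge)) 1e-8 else opts$ridge
  prior <- if (is.null(opts$prior)) NULL else opts$prior
  ws <- window_stats(features, assignment, counts)
  predicted <- numeric(W); flagged <- logical(W)
  for (d in seq_len(W)) {
    hold <- !is.na(assignment) & assignment == d
    if (sum(counts[-d]) == 0L || sum(ws$n0[-d]) == 0L) {
      fit <- full
      flagged[d] <- TRUE
    } else {
      fit <- fit_from_ws(drop_window_ws(ws, d), method, cov_center, ridge,
                         prior, colnames(features))
    }
    predicted[d] <- predict_window_count(fit, features[hold, , drop = FALSE])
  }
  if (any(flagged))
    warning(sum(flagged), " fold(s) had no positive training count; ",
            "full-data model used as fallback")
  out <- data.frame(window = windows$windows$index, kind = windows$windows$kind,
                    size = windows$windows$n_signals, observed = counts,
                    predicted = predicted, flagged = flagged)
  structure(out, class = c("count_lda_cv", "data.frame"),
            total_observed = sum(counts), total_predicted = sum(predicted))
}

#' @export
print.count_lda_cv <- function(x, ...) {
  cat("Leave-one-window-out cross-validation\n")
  cat(sprintf("  %d windows; total observed %d, total predicted %.1f\n",
              nrow(x), attr(x, "total_observed"), attr(x, "total_predicted")))
  NextMethod()
}

#' ROC curve over LDA posterior cut-offs
#'
#' Sweeps cut points downward from the maximum posterior, with the same
#' capped window-count accounting as [roc_parameter()].
#'
#' @param windows An `ae_windows` object.
#' @param model A fitted `count_lda` model, or a numeric vector of per-signal
#'   posteriors aligned with `windows$signals`.
#' @param cap Capped within-window counting (default `TRUE`).
#' @return A `roc_curve` object.
#' @export
roc_lda <- function(windows, model, cap = TRUE) {
  stopifnot(inherits(windows, "ae_windows"))
  probs <- if (inherits(model, "count_lda"))
    predict(model, windows$features, type = "posterior")
  else as.numeric(model)
  if (length(probs) != nrow(windows$signals))
    stop("posterior vector length does not match signals", call. = FALSE)
  roc_from_values(probs, windows$assignment, windows$windows$embolism_count, cap)
}
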