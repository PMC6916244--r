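# The count-weighted discriminant model.

test_that("the weighted estimator matches hand arithmetic on a tiny fixture", {
  ## two windows, sizes (4, 6), counts (2, 3); features small printed values
  f1 <- rbind(c(1, 2), c(2, 1), c(3, 3), c(2, 2))
  f2 <- rbind(c(5, 4), c(6, 5), c(4, 6), c(5, 5), c(6, 4), c(4, 5))
  colnames(f1) <- colnames(f2) <- c("p", "q")
  b <- windows_from_blocks(list(f1, f2), counts = c(2L, 3L))
  fit <- count_lda(b$features, b$assignment, b$counts)
  xb1 <- colMeans(f1); xb2 <- colMeans(f2)
  expect_equal(unname(fit$mu1), unname((2 * xb1 + 3 * xb2) / 5))
  expect_equal(unname(fit$mu0), unname((2 * xb1 + 3 * xb2) / 5))
  expect_equal(fit$prior1, 5 / 10)
})

test_that("pure windows reproduce supervised LDA exactly", {
  set.seed(31)
  cfg <- simulation_config()
  n <- 80
  f0 <- xylemAE:::draw_features(n, cfg$mu0, cfg$sigma)
  f1 <- xylemAE:::draw_features(n, cfg$mu1, cfg$sigma)
  b <- windows_from_blocks(list(f0[1:40, ], f0[41:80, ], f1[1:40, ], f1[41:80, ]),
                           counts = c(0L, 0L, 40L, 40L))
  fit <- count_lda(b$features, b$assignment, b$counts)
  ## textbook oracle: pooled class means and ML within-class covariance
  mu0 <- colMeans(f0); mu1 <- colMeans(f1)
  S <- (crossprod(sweep(f0, 2, mu0)) + crossprod(sweep(f1, 2, mu1))) / (2 * n)
  expect_equal(fit$mu0, mu0, tolerance = 1e-12)
  expect_equal(fit$mu1, mu1, tolerance = 1e-12)
  expect_equal(fit$sigma, S, tolerance = 1e-10)
  expect_equal(fit$prior1, 0.5)
})

test_that("posteriors follow Bayes rule with the fitted normal likelihoods", {
  set.seed(32)
  for (i in 1:25) {
    m <- random_lda_model()
    x <- matrix(rnorm(5 * 6), 5)
    direct <- posterior_oracle(m$mu0, m$mu1, m$sigma, m$prior1, x)
    expect_equal(predict(m, x), direct, tolerance = 1e-10)
  }
})

test_that("degenerate posteriors reduce to the prior and the midpoint to one half", {
  cfg <- simulation_config()
  b <- windows_from_blocks(
    list(xylemAE:::draw_features(30, cfg$mu0, cfg$sigma),
         xylemAE:::draw_features(30, cfg$mu0, cfg$sigma)),
    counts = c(5L, 0L))
  fit <- count_lda(b$features, b$assignment, b$counts)
  fit$mu1 <- fit$mu0   # uninformative likelihood
  a <- solve(fit$sigma, fit$mu1 - fit$mu0)
  fit$coefficients <- c(`(Intercept)` = -0.5 * sum((fit$mu1 + fit$mu0) * a) +
                          qlogis(fit$prior1), a)
  x <- matrix(rnorm(10 * 6, 10), 10)
  expect_equal(predict(fit, x), rep(fit$prior1, 10), tolerance = 1e-12)
  expect_equal(predict_window_count(fit, x), 10 * fit$prior1, tolerance = 1e-12)

  m <- random_lda_model()
  m$coefficients[1] <- m$coefficients[1] - qlogis(m$prior1)  # prior 0.5
  expect_equal(unname(predict(m, (m$mu0 + m$mu1) / 2)), 0.5, tolerance = 1e-12)
})

test_that("log-posterior-odds is affine in the features", {
  set.seed(33)
  m <- random_lda_model()
  x <- rnorm(6); y <- rnorm(6)
  for (lam in c(0, 0.25, 0.6, 1)) {
    lhs <- predict(m, lam * x + (1 - lam) * y, type = "logodds")
    rhs <- lam * predict(m, x, type = "logodds") +
      (1 - lam) * predict(m, y, type = "logodds")
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("window count predictions are conserved and bounded", {
  e <- simulate_experiment(small_config(seed = 34))
  w <- link_windows(filter_noise(e$signals), merge_nonevent_windows(e$schedule))
  fit <- count_lda(w)
  expect_true(all(fitted(fit) >= 0))
  expect_true(all(fitted(fit) <= w$windows$n_signals + 1e-9))
  expect_identical(predict_window_count(fit, w$features[0, , drop = FALSE]), 0)
  expect_equal(residuals(fit), w$windows$embolism_count - fitted(fit))
})

test_that("degenerate supervision errors are raised", {
  b <- windows_from_blocks(list(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3)),
                           counts = c(0L, 0L))
  expect_error(count_lda(b$features, b$assignment, b$counts), "all window counts are zero")
  expect_error(count_lda(b$features, b$assignment, c(2L, 6L)), "exceeding its size")
})

make_windows <- function(blocks, counts) {
  b <- windows_from_blocks(blocks, counts)
  structure(list(features = b$features, assignment = b$assignment,
                 signals = data.frame(TIME_S = seq_along(b$assignment)),
                 windows = data.frame(index = seq_along(counts), kind = "scan",
                                      embolism_count = counts,
                                      n_signals = as.integer(table(b$assignment))),
                 orphans = integer(0)), class = "ae_windows")
}

test_that("leave-one-window-out tracks observed counts for exchangeable windows", {
  set.seed(35)
  cfg <- simulation_config()
  blocks <- lapply(1:12, function(d)
    rbind(xylemAE:::draw_features(30, cfg$mu1, cfg$sigma),
          xylemAE:::draw_features(90, cfg$mu0, cfg$sigma)))
  cv <- loo_crossvalidate(make_windows(blocks, rep(30L, 12)))
  expect_true(all(abs(cv$predicted - cv$observed) / cv$observed < 0.35))
  expect_equal(attr(cv, "total_predicted"), sum(cv$predicted))
})

test_that("a held-out pure-background window predicts near zero under a recovered model", {
  set.seed(39)
  cfg <- simulation_config()
  ## widely separated classes so an accurate model gives near-zero
  ## background posteriors
  mu1 <- cfg$mu0 + 2.5 * (cfg$mu1 - cfg$mu0)
  n1_seq <- c(rep(c(10L, 25L, 45L, 60L), 3), 0L)  # contrast for identifiability
  blocks <- lapply(n1_seq, function(n1)
    rbind(xylemAE:::draw_features(n1, mu1, cfg$sigma),
          xylemAE:::draw_features(120L - n1, cfg$mu0, cfg$sigma)))
  ## the bias-corrected estimator recovers the class separation from the
  ## mixed windows; the weighted average alone would stay attenuated
  cv <- loo_crossvalidate(make_windows(blocks, n1_seq), method = "moment")
  expect_lt(cv$predicted[13], 0.05 * 120)
})

test_that("folds without positive counts fall back with a warning", {
  set.seed(36)
  cfg <- simulation_config()
  b <- windows_from_blocks(
    list(xylemAE:::draw_features(40, cfg$mu1, cfg$sigma),
         xylemAE:::draw_features(40, cfg$mu0, cfg$sigma),
         xylemAE:::draw_features(40, cfg$mu0, cfg$sigma)),
    counts = c(40L, 0L, 0L))
  w <- list(features = b$features, assignment = b$assignment,
            signals = data.frame(TIME_S = seq_along(b$assignment)),
            windows = data.frame(index = 1:3, kind = "scan",
                                 embolism_count = b$counts,
                                 n_signals = c(40L, 40L, 40L)),
            orphans = integer(0))
  class(w) <- "ae_windows"
  expect_warning(cv <- loo_crossvalidate(w), "fallback")
  expect_true(cv$flagged[1])
})

test_that("LDA ROC dominates single-parameter ROC curves on a mid-separation run", {
  cfg <- simulation_config(seed = 8, total_duration_h = 24,
                           background_uniform_frac = 1,
                           background_rate_per_min = 3,
                           total_expected_embolisms = 250)
  e <- simulate_experiment(cfg)
  w <- link_windows(filter_noise(e$signals), merge_nonevent_windows(e$schedule))
  fit <- count_lda(w)
  auc_lda <- roc_auc(roc_lda(w, fit))
  for (p in c("AMP", "COUN", "DURATION", "SIGSTRNGTH", "ABSENERGY", "FREQPP2"))
    expect_gt(auc_lda, roc_auc(roc_parameter(w, p)))

  ## oracle probabilities reach perfect classification
  keep <- !is.na(w$assignment)
  lab <- e$truth$label[e$signals$AMP > 28]
  roc_oracle <- roc_lda(w, as.numeric(lab))
  cv <- roc_oracle$curve
  expect_true(any(cv$tpr > 0.99 & cv$fpr < 0.01))

  ## constant posteriors give a diagonal curve
  roc_const <- roc_lda(w, rep(0.2, nrow(w$signals)))
  expect_equal(roc_auc(roc_const), 0.5, tolerance = 0.01)
})

test_that("the generative simulate method reproduces the fitted moments", {
  set.seed(37)
  m <- random_lda_model()
  s <- simulate(m, nsim = 20000, seed = 38)
  expect_lt(abs(mean(s$label) - m$prior1), 0.02)
  x1 <- as.matrix(s[s$label == 1, 1:6])
  se <- sqrt(diag(m$sigma) / nrow(x1))
  expect_true(all(abs(colMeans(x1) - m$mu1) < 4 * se))
})
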