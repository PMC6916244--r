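# Shared fixtures: small, fast synthetic configurations.

## A short drydown: ~12 h, modest signal counts, noise-free psi points.
## Arguments in ... override the fixture defaults.
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(seed = seed, total_duration_h = 12,
                                 background_rate_per_min = 2,
                                 total_expected_embolisms = 120,
                                 psi_sampling_h = seq(0, 12, by = 1),
                                 psi_noise_sd = 0),
                            list(...))
  do.call(simulation_config, args)
}

## Small image geometry for the microCT tests.
image_config <- function(seed = 5L, ...) {
  args <- utils::modifyList(list(seed = seed, image_size = 128L,
                                 image_n_vessels = 80L, image_n_slices = 9L),
                            list(...))
  do.call(simulation_config, args)
}

## A hand-buildable set of labelled windows from explicit per-window
## feature matrices and counts.
windows_from_blocks <- function(blocks, counts) {
  features <- do.call(rbind, blocks)
  assignment <- rep(seq_along(blocks), vapply(blocks, nrow, integer(1)))
  list(features = features, assignment = assignment, counts = counts)
}

## Direct (Bayes rule) posterior with explicitly computed normal densities -
## the brute-force oracle for the discriminant path.
posterior_oracle <- function(mu0, mu1, sigma, prior1, x) {
  dens <- function(xx, mu) {
    q <- stats::mahalanobis(xx, mu, sigma)
    exp(-0.5 * q) / sqrt((2 * pi)^length(mu) * det(sigma))
  }
  d1 <- prior1 * dens(x, mu1)
  d0 <- (1 - prior1) * dens(x, mu0)
  d1 / (d1 + d0)
}

## Random well-conditioned LDA model in p dimensions.
random_lda_model <- function(p = 6L) {
  A <- matrix(rnorm(p * p), p)
  sigma <- crossprod(A) + diag(p)
  mu0 <- rnorm(p); mu1 <- mu0 + rnorm(p)
  prior1 <- runif(1, 0.05, 0.95)
  a <- solve(sigma, mu1 - mu0)
  b <- -0.5 * sum((mu1 + mu0) * a) + qlogis(prior1)
  structure(list(mu0 = mu0, mu1 = mu1, sigma = sigma, prior1 = prior1,
                 coefficients = c(`(Intercept)` = b, a),
                 features = paste0("f", seq_len(p))),
            class = "count_lda")
}
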