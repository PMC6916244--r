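# Synthetic dehydration experiments with known ground truth.
#
# The generator emulates the structure of a combined AE / microCT drydown:
# a scanning timeline of 4-min rotations grouped into 24-min runs separated by
# 6-min (day) or 30-min (night) breaks; embolism events arriving as an
# inhomogeneous Poisson process whose intensity follows a logistic curve in the
# (strain-mapped) xylem water potential; AE feature vectors drawn from the
# two-class shared-covariance normal model underlying linear discriminant
# analysis; and a three-segment linear stress-strain relation tying dendrometer
# strain to water potential.

#' Configuration for a synthetic AE / microCT dehydration experiment
#'
#' Collects every knob of the synthetic-experiment generator and validates the
#' joint constraints (positive-definite covariance, embolism budget, partial
#' power simplex). Defaults describe a four-day drydown of a small diffuse
#' stem with 1100 vessels, 541 of them natively embolized, an expected 457 new
#' embolism events, and a background AE rate chosen so that roughly 25,000
#' non-embolism hits are recorded - the regime in which weak count supervision
#' is hard but informative.
#'
#' @param seed Master integer seed; all generator randomness derives from it.
#' @param total_duration_h Experiment length in hours.
#' @param n_rotations Rotations per scan run.
#' @param rotation_min Minutes per rotation (one tomogram).
#' @param day_break_min,night_break_min Break length between runs, minutes.
#' @param day_start_h,day_end_h Local hours delimiting "daytime" breaks; the
#'   experiment clock starts at `day_start_h`.
#' @param window_unit `"run"` labels one window per 24-min scan run (plus one
#'   per break); `"rotation"` labels every 4-min rotation separately.
#' @param n_vessels_total Vessels on the anatomical cross-section.
#' @param n_native_embolized Vessels already gas-filled at the start.
#' @param total_expected_embolisms Expected number of new embolism events over
#'   the run (the logistic hazard is normalized to this total).
#' @param embolism_hazard Optional function of time (seconds) giving an
#'   instantaneous embolism rate (events per second). When `NULL` the default
#'   logistic-in-psi hazard is used.
#' @param psi50_hazard,psi_scale_hazard Midpoint (MPa) and scale of the default
#'   logistic hazard in water potential.
#' @param background_rate_per_min Mean non-embolism AE hits per minute; either
#'   a scalar or a function of time in seconds returning a rate per minute.
#' @param background_uniform_frac With a scalar rate, the fraction of
#'   background intensity that is uniform in time; the remainder follows the
#'   embolism hazard density (non-embolism AE sources track the drydown, which
#'   is why even unfiltered acoustic curves resemble the microCT curve).
#' @param mu0,mu1 Length-6 class mean vectors for the feature order
#'   (AMP dB, COUN, DURATION us, SIGSTRNGTH nVs, ABSENERGY aJ, FREQPP2 %).
#' @param sigma 6x6 shared feature covariance (symmetric positive definite).
#' @param contamination_fraction Proportion of background hits replaced by
#'   heavy-tailed outliers (deviations inflated by `contamination_scale`).
#' @param contamination_scale Inflation factor for contaminated deviations.
#' @param strain_model List with `intercept`, `slopes` (3), `breakpoints` (2,
#'   strain units) and `strain_max` describing the three-segment linear
#'   psi(strain) relation.
#' @param psi_sampling_h Times (hours) of point water-potential measurements.
#' @param psi_noise_sd Gaussian noise on the point psi measurements (MPa).
#' @param image_size,image_n_vessels,image_n_slices,vessel_radius_range
#'   Geometry of synthetic microCT stacks (pixels, discs, slices).
#' @param grey_level,embolized_level,matrix_level 8-bit grey values for
#'   water-filled vessels, gas-filled vessels and the woody matrix.
#' @param image_noise_sd Per-slice additive Gaussian noise (grey values).
#' @param image_drift_px Maximum per-stack rigid drift (pixels, per axis).
#' @param pixel_pitch_um Nominal pixel pitch (micrometres).
#'
#' @return An object of class `simulation_config`.
#' @seealso [simulate_experiment()], [simulate_image_series()]
#' @export
simulation_config <- function(seed = 1L,
                              total_duration_h = 96,
                              n_rotations = 6L,
                              rotation_min = 4,
                              day_break_min = 6,
                              night_break_min = 30,
                              day_start_h = 6,
                              day_end_h = 22,
                              window_unit = c("rotation", "run"),
                              n_vessels_total = 1100L,
                              n_native_embolized = 541L,
                              total_expected_embolisms = 457,
                              embolism_hazard = NULL,
                              psi50_hazard = -2.3,
                              psi_scale_hazard = 0.45,
                              background_rate_per_min = 4.4,
                              background_uniform_frac = 0.3,
                              mu0 = c(AMP = 36, COUN = 15, DURATION = 300,
                                      SIGSTRNGTH = 3.0, ABSENERGY = 12, FREQPP2 = 28),
                              mu1 = c(AMP = 44, COUN = 27, DURATION = 520,
                                      SIGSTRNGTH = 5.2, ABSENERGY = 22, FREQPP2 = 45),
                              sigma = NULL,
                              contamination_fraction = 0.02,
                              contamination_scale = 4,
                              strain_model = list(intercept = -0.2,
                                                  slopes = c(-1.2, -2.0, -3.5),
                                                  breakpoints = c(0.5, 1.2),
                                                  strain_max = 2.3),
                              psi_sampling_h = NULL,
                              psi_noise_sd = 0.05,
                              image_size = 256L,
                              image_n_vessels = 300L,
                              image_n_slices = 50L,
                              vessel_radius_range = c(2, 6),
                              grey_level = 140,
                              embolized_level = 30,
                              matrix_level = 180,
                              image_noise_sd = 3,
                              image_drift_px = 1.5,
                              pixel_pitch_um = 7.5) {
  window_unit <- match.arg(window_unit)
  if (is.null(sigma)) sigma <- default_feature_sigma()
  if (is.null(psi_sampling_h)) psi_sampling_h <- seq(0, total_duration_h, by = 6)
  if (!is_square_spd(sigma) || nrow(sigma) != 6L)
    stop_config("sigma must be a symmetric positive-definite 6x6 matrix")
  if (length(mu0) != 6L || length(mu1) != 6L)
    stop_config("mu0 and mu1 must be length-6 feature mean vectors")
  if (n_native_embolized > n_vessels_total)
    stop_config("more native embolized vessels than vessels")
  avail <- n_vessels_total - n_native_embolized
  if (is.null(embolism_hazard) && total_expected_embolisms > avail)
    stop_config("expected embolisms (", total_expected_embolisms,
                ") exceed available vessels (", avail, ")")
  if (contamination_fraction < 0 || contamination_fraction >= 1)
    stop_config("contamination_fraction must be in [0, 1)")
  if (background_uniform_frac < 0 || background_uniform_frac > 1)
    stop_config("background_uniform_frac must be in [0, 1]")
  sm <- strain_model
  if (!all(c("intercept", "slopes", "breakpoints", "strain_max") %in% names(sm)) ||
      length(sm$slopes) != 3L || length(sm$breakpoints) != 2L ||
      sm$breakpoints[1] >= sm$breakpoints[2])
    stop_config("strain_model needs intercept, 3 slopes and 2 increasing breakpoints")
  cfg <- list(seed = as.integer(seed), total_duration_h = total_duration_h,
              n_rotations = as.integer(n_rotations), rotation_min = rotation_min,
              day_break_min = day_break_min, night_break_min = night_break_min,
              day_start_h = day_start_h, day_end_h = day_end_h,
              window_unit = window_unit,
              n_vessels_total = as.integer(n_vessels_total),
              n_native_embolized = as.integer(n_native_embolized),
              total_expected_embolisms = total_expected_embolisms,
              embolism_hazard = embolism_hazard,
              psi50_hazard = psi50_hazard, psi_scale_hazard = psi_scale_hazard,
              background_rate_per_min = background_rate_per_min,
              background_uniform_frac = background_uniform_frac,
              mu0 = setNames(as.numeric(mu0), AE_FEATURES),
              mu1 = setNames(as.numeric(mu1), AE_FEATURES),
              sigma = sigma,
              contamination_fraction = contamination_fraction,
              contamination_scale = contamination_scale,
              strain_model = sm, psi_sampling_h = psi_sampling_h,
              psi_noise_sd = psi_noise_sd,
              image_size = as.integer(image_size),
              image_n_vessels = as.integer(image_n_vessels),
              image_n_slices = as.integer(image_n_slices),
              vessel_radius_range = vessel_radius_range,
              grey_level = grey_level, embolized_level = embolized_level,
              matrix_level = matrix_level, image_noise_sd = image_noise_sd,
              image_drift_px = image_drift_px, pixel_pitch_um = pixel_pitch_um)
  class(cfg) <- "simulation_config"
  cfg
}

## Default shared covariance: the energetic parameters (AMP, COUN, DURATION,
## SIGSTRNGTH, ABSENERGY) positively inter-correlated, FREQPP2 mildly
## anti-correlated with AMP and COUN - the correlation structure reported for
## dehydrating ash stems.
default_feature_sigma <- function() {
  sds <- c(AMP = 4, COUN = 5, DURATION = 90, SIGSTRNGTH = 0.9,
           ABSENERGY = 4, FREQPP2 = 7)
  R <- matrix(c(
    1.0, 0.6, 0.5, 0.6, 0.6, -0.3,
    0.6, 1.0, 0.5, 0.5, 0.5, -0.3,
    0.5, 0.5, 1.0, 0.5, 0.4, -0.1,
    0.6, 0.5, 0.5, 1.0, 0.7, -0.1,
    0.6, 0.5, 0.4, 0.7, 1.0, -0.1,
    -0.3, -0.3, -0.1, -0.1, -0.1, 1.0), 6, 6)
  s <- diag(sds) %*% R %*% diag(sds)
  dimnames(s) <- list(AE_FEATURES, AE_FEATURES)
  s
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic AE/microCT experiment configuration\n")
  cat(sprintf("  duration: %g h, windows per %s, seed %d\n",
              x$total_duration_h, x$window_unit, x$seed))
  cat(sprintf("  vessels: %d total, %d native embolized, E[new events] = %g\n",
              x$n_vessels_total, x$n_native_embolized, x$total_expected_embolisms))
  cat(sprintf("  background rate: %s hits/min, contamination %.1f%%\n",
              if (is.function(x$background_rate_per_min)) "time-varying"
              else format(x$background_rate_per_min), 100 * x$contamination_fraction))
  invisible(x)
}

#' Scanning timeline of alternating scan and break windows
#'
#' Builds the window schedule: runs of `n_rotations` x `rotation_min` scanning
#' followed by a 6-min (day) or 30-min (night) break, repeated over the
#' experiment. With `window_unit = "rotation"` each rotation is its own scan
#' window; with `"run"` a whole run is one window.
#'
#' @param config A [simulation_config()].
#' @return A data frame with columns `index`, `start_s`, `end_s`, `kind`.
#' @export
make_schedule <- function(config) {
  total_s <- config$total_duration_h * 3600
  run_s <- config$n_rotations * config$rotation_min * 60
  rot_s <- config$rotation_min * 60
  day_len <- (config$day_end_h - config$day_start_h) %% 24
  start <- numeric(0); end <- numeric(0); kind <- character(0)
  t <- 0
  while (t < total_s) {
    if (config$window_unit == "rotation") {
      for (r in seq_len(config$n_rotations)) {
        if (t >= total_s) break
        e <- min(t + rot_s, total_s)
        start <- c(start, t); end <- c(end, e); kind <- c(kind, "scan")
        t <- e
      }
    } else {
      e <- min(t + run_s, total_s)
      start <- c(start, t); end <- c(end, e); kind <- c(kind, "scan")
      t <- e
    }
    if (t >= total_s) break
    ## time of day at break start, measured from midnight
    tod_h <- (config$day_start_h + t / 3600) %% 24
    is_day <- if (config$day_start_h <= config$day_end_h)
      tod_h >= config$day_start_h && tod_h < config$day_end_h
    else tod_h >= config$day_start_h || tod_h < config$day_end_h
    brk <- if (is_day) config$day_break_min else config$night_break_min
    e <- min(t + brk * 60, total_s)
    start <- c(start, t); end <- c(end, e); kind <- c(kind, "break")
    t <- e
  }
  data.frame(index = seq_along(start), start_s = start, end_s = end,
             kind = kind, stringsAsFactors = FALSE)
}

## psi as a function of strain under the three-segment linear model.
psi_from_strain <- function(sm, strain) {
  b1 <- sm$breakpoints[1]; b2 <- sm$breakpoints[2]
  s <- sm$slopes
  sm$intercept + s[1] * pmin(strain, b1) +
    s[2] * pmin(pmax(strain - b1, 0), b2 - b1) +
    s[3] * pmax(strain - b2, 0)
}

## Monotone saturating strain trajectory over the experiment.
strain_at_time <- function(config, t_s) {
  total_s <- config$total_duration_h * 3600
  k <- 2
  config$strain_model$strain_max * (1 - exp(-k * t_s / total_s)) / (1 - exp(-k))
}

psi_at_time <- function(config, t_s) {
  psi_from_strain(config$strain_model, strain_at_time(config, t_s))
}

## Expected number of new embolism events per schedule window.
expected_window_embolisms <- function(config, schedule) {
  if (is.function(config$embolism_hazard)) {
    sapply(seq_len(nrow(schedule)), function(i) {
      tt <- seq(schedule$start_s[i], schedule$end_s[i], length.out = 21)
      mean(config$embolism_hazard(tt)) * (schedule$end_s[i] - schedule$start_s[i])
    })
  } else {
    ## logistic cumulative in mapped psi, normalized so the in-window
    ## expectations sum exactly to total_expected_embolisms
    Fc <- function(t) plogis((config$psi50_hazard - psi_at_time(config, t)) /
                               config$psi_scale_hazard)
    f0 <- Fc(0); f1 <- Fc(config$total_duration_h * 3600)
    cum <- (Fc(c(schedule$start_s, schedule$end_s[nrow(schedule)])) - f0) / (f1 - f0)
    config$total_expected_embolisms * diff(cum)
  }
}

## Normalized CDF of event times under the configured hazard, on a 1-min
## grid; NULL when the hazard is degenerate (zero mass).
hazard_time_cdf <- function(config, total_s) {
  t <- seq(0, total_s, length.out = max(200L, ceiling(total_s / 60)))
  if (is.function(config$embolism_hazard)) {
    dens <- pmax(config$embolism_hazard(t), 0)
    Fv <- cumsum(dens)
  } else {
    if (config$total_expected_embolisms <= 0) return(NULL)
    Fv <- plogis((config$psi50_hazard - psi_at_time(config, t)) /
                   config$psi_scale_hazard)
    Fv <- Fv - Fv[1]
  }
  if (max(Fv) <= 0) return(NULL)
  Fv <- Fv / max(Fv)
  ## strictly increasing for inverse interpolation
  Fv <- Fv + seq_along(Fv) * 1e-12
  list(t = t, F = Fv / max(Fv))
}

## Draw per-window embolism counts (Poisson, truncated at the vessel budget).
draw_window_counts <- function(config, schedule) {
  lambda <- expected_window_embolisms(config, schedule)
  if (any(lambda < -1e-9)) stop_config("embolism hazard must be non-negative")
  counts <- rpois(length(lambda), pmax(lambda, 0))
  avail <- config$n_vessels_total - config$n_native_embolized
  cum <- cumsum(counts)
  if (any(cum > avail)) {
    over <- which(cum > avail)[1]
    counts[over] <- counts[over] - (cum[over] - avail)
    if (over < length(counts)) counts[(over + 1):length(counts)] <- 0L
  }
  as.integer(counts)
}

## Sample n signals of one class; contamination inflates deviations about mu.
draw_features <- function(n, mu, sigma, contamination_fraction = 0,
                          contamination_scale = 1) {
  if (n == 0L) return(matrix(numeric(0), 0, length(mu),
                             dimnames = list(NULL, names(mu))))
  x <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  if (n == 1L) x <- matrix(x, 1, dimnames = list(NULL, names(mu)))
  if (contamination_fraction > 0) {
    bad <- runif(n) < contamination_fraction
    if (any(bad))
      x[bad, ] <- sweep(sweep(x[bad, , drop = FALSE], 2, mu, "-") *
                          contamination_scale, 2, mu, "+")
  }
  colnames(x) <- names(mu)
  x
}

## The 12 nuisance waveform parameters: independent log-normals in plausible
## instrument ranges, plus the partial-power simplex completed around FREQPP2.
draw_nuisance <- function(n, freqpp2) {
  ln <- function(m, s) rlnorm(n, log(m), s)
  rest <- pmax(100 - freqpp2, 0)
  ## Dirichlet(2, 1.5, 1) split of the remaining spectral mass
  g <- cbind(rgamma(n, 2), rgamma(n, 1.5), rgamma(n, 1))
  g <- g / pmax(rowSums(g), .Machine$double.eps)
  data.frame(RISE = ln(30, 0.6), ENER = ln(20, 0.8), AFRQ = ln(150, 0.3),
             RMS = ln(2, 0.5), ASL = ln(25, 0.2), RFRQ = ln(120, 0.3),
             IFRQ = ln(180, 0.3),
             FREQPP1 = rest * g[, 1], FREQPP3 = rest * g[, 2],
             FREQPP4 = rest * g[, 3],
             FRQC = ln(200, 0.25), PFRQ = ln(150, 0.35))
}

#' Simulate a complete synthetic AE / microCT experiment
#'
#' Draws the scan/break schedule, per-window embolism counts (inhomogeneous
#' Poisson against the configured hazard), AE feature vectors from the
#' two-class shared-covariance normal model (with optional heavy-tailed
#' background contamination), the 12 nuisance waveform parameters, the
#' dendrometer strain trace and the point water-potential measurements.
#' Hidden per-signal class labels and the true event times are returned as
#' ground truth - information a real experiment never observes directly.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ae_experiment`: list with `config`, `signals`
#'   (data frame `TIME_S` + the 18 waveform parameters, time-ordered),
#'   `schedule` (windows with true `embolism_count`), `truth` (per-signal
#'   0/1 labels aligned with `signals`, and embolism event times), `strain`
#'   (per-minute trace) and `psi_points`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- child_seeds(config$seed, 4L)
  schedule <- make_schedule(config)
  total_s <- config$total_duration_h * 3600

  set.seed(seeds[1])
  counts <- draw_window_counts(config, schedule)

  ## embolism event times: uniform within their window
  emb_times <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    if (counts[i] == 0L) return(numeric(0))
    sort(runif(counts[i], schedule$start_s[i], schedule$end_s[i]))
  }))
  n1 <- length(emb_times)

  ## background hits: inhomogeneous Poisson over the full span. With a scalar
  ## mean rate, a uniform floor plus a component following the embolism hazard
  ## density (dehydration-related AE sources wax and wane with the drydown).
  set.seed(seeds[2])
  rate <- config$background_rate_per_min
  if (is.function(rate)) {
    grid <- seq(0, total_s, by = 60)
    rmax <- max(rate(grid)) / 60
    n_cand <- rpois(1, rmax * total_s)
    cand <- runif(n_cand, 0, total_s)
    keep <- runif(n_cand) < (rate(cand) / 60) / rmax
    bg_times <- sort(cand[keep])
  } else {
    expected_total <- rate / 60 * total_s
    frac_u <- config$background_uniform_frac
    cdf <- hazard_time_cdf(config, total_s)
    if (is.null(cdf)) frac_u <- 1
    n_u <- rpois(1, frac_u * expected_total)
    t_u <- runif(n_u, 0, total_s)
    t_h <- numeric(0)
    if (frac_u < 1) {
      n_h <- rpois(1, (1 - frac_u) * expected_total)
      u <- runif(n_h)
      t_h <- approx(cdf$F, cdf$t, xout = u, rule = 2)$y
    }
    bg_times <- sort(c(t_u, t_h))
  }
  n0 <- length(bg_times)

  set.seed(seeds[3])
  f1 <- draw_features(n1, config$mu1, config$sigma)
  f0 <- draw_features(n0, config$mu0, config$sigma,
                      config$contamination_fraction, config$contamination_scale)
  times <- c(emb_times, bg_times)
  label <- c(rep(1L, n1), rep(0L, n0))
  feats <- rbind(f1, f0)

  set.seed(seeds[4])
  ## physical floors; parameters are non-negative by construction on hardware
  feats[, "AMP"] <- pmax(feats[, "AMP"], 0)
  feats[, "COUN"] <- pmax(feats[, "COUN"], 0)
  feats[, "DURATION"] <- pmax(feats[, "DURATION"], 0)
  feats[, "SIGSTRNGTH"] <- pmax(feats[, "SIGSTRNGTH"], 0)
  feats[, "ABSENERGY"] <- pmax(feats[, "ABSENERGY"], 0)
  feats[, "FREQPP2"] <- pmin(pmax(feats[, "FREQPP2"], 0), 100)
  nuis <- draw_nuisance(nrow(feats), feats[, "FREQPP2"])

  signals <- data.frame(TIME_S = times,
                        RISE = nuis$RISE, COUN = feats[, "COUN"],
                        ENER = nuis$ENER, DURATION = feats[, "DURATION"],
                        AMP = feats[, "AMP"], AFRQ = nuis$AFRQ, RMS = nuis$RMS,
                        ASL = nuis$ASL, RFRQ = nuis$RFRQ, IFRQ = nuis$IFRQ,
                        SIGSTRNGTH = feats[, "SIGSTRNGTH"],
                        ABSENERGY = feats[, "ABSENERGY"],
                        FREQPP1 = nuis$FREQPP1, FREQPP2 = feats[, "FREQPP2"],
                        FREQPP3 = nuis$FREQPP3, FREQPP4 = nuis$FREQPP4,
                        FRQC = nuis$FRQC, PFRQ = nuis$PFRQ)
  ord <- order(signals$TIME_S)
  signals <- signals[ord, , drop = FALSE]
  rownames(signals) <- NULL
  label <- label[ord]

  schedule$embolism_count <- counts

  strain_t <- seq(0, total_s, by = 60)
  strain <- data.frame(time_s = strain_t,
                       strain = strain_at_time(config, strain_t))
  psi_t <- pmin(config$psi_sampling_h * 3600, total_s)
  psi <- psi_at_time(config, psi_t) +
    if (config$psi_noise_sd > 0) rnorm(length(psi_t), 0, config$psi_noise_sd) else 0
  psi_points <- data.frame(time_s = psi_t, psi_mpa = psi)

  structure(list(config = config, signals = signals, schedule = schedule,
                 truth = list(label = label, embolism_times = emb_times),
                 strain = strain, psi_points = psi_points),
            class = "ae_experiment")
}

#' @export
print.ae_experiment <- function(x, ...) {
  cat("Synthetic AE/microCT experiment\n")
  cat(sprintf("  %d AE signals (%d embolism, %d background) over %g h\n",
              nrow(x$signals), sum(x$truth$label), sum(1 - x$truth$label),
              x$config$total_duration_h))
  cat(sprintf("  %d schedule windows (%d scan, %d break), %d microCT events\n",
              nrow(x$schedule), sum(x$schedule$kind == "scan"),
              sum(x$schedule$kind == "break"), sum(x$schedule$embolism_count)))
  invisible(x)
}

## ---- synthetic microCT stacks -------------------------------------------

## Pack n discs of radius in `rr` inside a cross-section disc by rejection.
pack_vessels <- function(n, size, rr, section_radius) {
  cx <- (size + 1) / 2
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < 200000L) {
    tries <- tries + 1L
    r <- runif(1, rr[1], rr[2])
    a <- runif(1, 0, 2 * pi)
    d <- sqrt(runif(1)) * (section_radius - r - 2)
    x <- cx + d * cos(a); y <- cx + d * sin(a)
    if (all((xs - x)^2 + (ys - y)^2 > (rs + r + 1.5)^2)) {
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    }
  }
  if (length(xs) < n)
    stop_config("could not pack ", n, " vessels into the cross-section; ",
                "reduce image_n_vessels or enlarge image_size")
  data.frame(x = xs, y = ys, r = rs)
}

## Paint the cross-section: matrix disc with vessel discs at given grey
## levels. Disc edges are anti-aliased by sub-pixel coverage so that small
## rigid drifts displace smooth edges rather than aliased ones.
paint_section <- function(size, vessels, levels, matrix_level, section_radius) {
  cx <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  dist_c <- sqrt((rows - cx)^2 + (cols - cx)^2)
  cover <- pmin(pmax(section_radius - dist_c + 0.5, 0), 1)
  img <- matrix_level * cover
  for (i in seq_len(nrow(vessels))) {
    rr <- vessels$r[i]
    r0 <- max(1, floor(vessels$y[i] - rr - 1)); r1 <- min(size, ceiling(vessels$y[i] + rr + 1))
    c0 <- max(1, floor(vessels$x[i] - rr - 1)); c1 <- min(size, ceiling(vessels$x[i] + rr + 1))
    sub <- expand.grid(r = r0:r1, c = c0:c1)
    dd <- sqrt((sub$r - vessels$y[i])^2 + (sub$c - vessels$x[i])^2)
    cv <- pmin(pmax(rr - dd + 0.5, 0), 1)
    idx <- cbind(sub$r, sub$c)
    img[idx] <- img[idx] + cv * (levels[i] - img[idx])
  }
  img
}

#' Simulate microCT slice stacks with planted embolism transitions
#'
#' Builds one stack per time point (one before the first window plus one after
#' each window). The cross-section is a disc-packed field of vessel discs on a
#' brighter woody matrix; exactly `counts[w]` vessels switch from water-filled
#' grey to gas-filled black between stacks `w` and `w+1`. Optional per-slice
#' Gaussian noise and a small rigid drift per stack emulate acquisition
#' imperfections. Planted vessel coordinates and per-stack drifts are returned
#' as ground truth. All image levels are arbitrary fixture values.
#'
#' @param config A [simulation_config()].
#' @param counts Integer vector of embolism events per window.
#' @return List of class `uct_series`: `stacks` (each a 3D array
#'   `[row, col, slice]`), `coords` (data frame `window`, `x`, `y` of planted
#'   transitions, in the undrifted frame), `drift` (per-stack `dx`, `dy`), and
#'   `pixel_pitch_um`.
#' @export
simulate_image_series <- function(config, counts) {
  stopifnot(inherits(config, "simulation_config"))
  counts <- as.integer(counts)
  if (any(counts < 0)) stop_config("negative embolism count")
  seeds <- child_seeds(config$seed + 7L, 2L)
  set.seed(seeds[1])
  size <- config$image_size
  section_radius <- size * 0.46
  vess <- pack_vessels(config$image_n_vessels, size,
                       config$vessel_radius_range, section_radius)
  n_trans <- sum(counts)
  if (n_trans > nrow(vess))
    stop("more transitions requested (", n_trans, ") than grey vessels (",
         nrow(vess), ")", call. = FALSE)
  chosen <- sample.int(nrow(vess), n_trans)
  window_of <- rep(seq_along(counts), counts)

  set.seed(seeds[2])
  n_stacks <- length(counts) + 1L
  ## every stack (including the first) carries its own rigid drift, as a
  ## real sample repositioned between scans would
  drift <- cbind(dx = runif(n_stacks, -config$image_drift_px,
                            config$image_drift_px),
                 dy = runif(n_stacks, -config$image_drift_px,
                            config$image_drift_px))
  stacks <- vector("list", n_stacks)
  for (s in seq_len(n_stacks)) {
    emb <- chosen[window_of <= (s - 1L)]
    levels <- rep(config$grey_level, nrow(vess))
    levels[emb] <- config$embolized_level
    base <- paint_section(size, vess, levels, config$matrix_level, section_radius)
    if (drift[s, "dx"] != 0 || drift[s, "dy"] != 0)
      base <- shift_image(base, drift[s, "dx"], drift[s, "dy"])
    arr <- array(0, dim = c(size, size, config$image_n_slices))
    for (k in seq_len(config$image_n_slices)) {
      sl <- base
      if (config$image_noise_sd > 0)
        sl <- sl + matrix(rnorm(size * size, 0, config$image_noise_sd), size, size)
      arr[, , k] <- sl
    }
    stacks[[s]] <- arr
  }
  structure(list(stacks = stacks,
                 coords = data.frame(window = window_of,
                                     x = vess$x[chosen], y = vess$y[chosen]),
                 drift = drift, pixel_pitch_um = config$pixel_pitch_um),
            class = "uct_series")
}

#' @export
print.uct_series <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat(sprintf("microCT series: %d stacks of %dx%d px, %d slices; %d planted transitions\n",
              length(x$stacks), d[1], d[2], d[3], nrow(x$coords)))
  invisible(x)
}
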