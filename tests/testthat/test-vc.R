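# Cumulation, derivatives, endpoint rule, rescaling, stress-strain mapping,
# vulnerability values and curve comparison.

test_that("cumulation steps and averages match a brute-force prefix sum", {
  cc <- cumulate(c(100, 200, 300), bin_minutes = 10, t_range = c(0, 1200))
  expect_equal(cc$value[2], 3)
  expect_true(all(diff(cc$value) >= 0))

  cp <- cumulate(c(100, 500), weights = c(0.2, 0.3), bin_minutes = 10,
                 t_range = c(0, 1200))
  expect_equal(cp$value[nrow(cp)], 0.5)

  ## random stream against an independent minute-grid prefix-sum rebinning
  set.seed(41)
  times <- sort(runif(300, 0, 7200))
  cc2 <- cumulate(times, bin_minutes = 10, t_range = c(0, 7200))
  grid <- seq(30, 7200 - 30, by = 60)
  prefix <- vapply(grid, function(g) sum(times <= g), numeric(1))
  oracle <- vapply(seq_len(12), function(b)
    mean(prefix[grid > (b - 1) * 600 & grid < b * 600]), numeric(1))
  expect_equal(cc2$value, oracle)

  z <- cumulate(numeric(0), t_range = c(0, 3600))
  expect_true(all(z$value == 0))
  expect_error(cumulate(numeric(0)), "t_range")
})

test_that("windowed least-squares derivatives recover analytic slopes", {
  a <- 2e-10
  tt <- seq(300, 48 * 3600 - 300, by = 600)
  cubic <- data.frame(time_s = tt, value = a * tt^3)
  d3 <- moving_derivative(cubic, 3, window_minutes = 600)
  ok <- !is.na(d3$value)
  expect_true(any(ok))
  expect_lt(max(abs(d3$value[ok] - 6 * a) / (6 * a)), 0.02)

  lin <- data.frame(time_s = tt, value = 5 + 0.01 * tt)
  d1 <- moving_derivative(lin, 1, 120)
  expect_equal(d1$value[!is.na(d1$value)],
               rep(0.01, sum(!is.na(d1$value))), tolerance = 1e-9)
  d3l <- moving_derivative(lin, 3, 600)
  expect_lt(max(abs(d3l$value), na.rm = TRUE), 1e-15)

  expect_error(moving_derivative(cubic, 1, 1e5), "longer than the series")
})

test_that("derivatives of a noisy sigmoid agree with a smoothing-spline oracle", {
  set.seed(42)
  tt <- seq(300, 96 * 3600, by = 600)
  cum <- 457 * plogis((tt - 40 * 3600) / (6 * 3600)) + rnorm(length(tt), 0, 0.5)
  cum <- cummax(cum)
  curve <- data.frame(time_s = tt, value = cum)
  d1 <- moving_derivative(curve, 1, 120)
  sp <- smooth.spline(tt, cum)
  oracle <- predict(sp, tt, deriv = 1)$y
  mid <- which(!is.na(d1$value))
  mid <- mid[mid > 20 & mid < length(tt) - 20]
  scale <- max(abs(oracle))
  expect_lt(median(abs(d1$value[mid] - oracle[mid])) / scale, 0.05)
})

test_that("the endpoint rule finds the post-peak third-derivative maximum", {
  tt <- seq(300, 96 * 3600, by = 600)
  cum <- 457 * plogis((tt - 40 * 3600) / (6 * 3600))
  cc <- structure(data.frame(time_s = tt, value = cum),
                  class = c("cum_curve", "data.frame"))
  ep <- find_endpoint(cc, 15, 90)
  ## numeric oracle: repeated central differences, first local max after the
  ## activity peak
  v <- cum; h <- 600
  d1o <- (c(v[-1], NA) - c(NA, v[-length(v)])) / (2 * h)
  t_star <- tt[which.max(d1o)]
  d3o <- v
  for (k in 1:3) d3o <- (c(d3o[-1], NA) - c(NA, d3o[-length(d3o)])) / (2 * h)
  cand <- which(tt > t_star)
  lm3 <- cand[which(d3o[cand] > c(NA, d3o)[cand] & d3o[cand] > d3o[cand + 1])][1]
  expect_lt(abs(ep - tt[lm3]), 600 + 1e-9)

  ## strictly accelerating cumulative curve: endpoint undefined
  acc <- structure(data.frame(time_s = tt, value = exp(tt / (8 * 3600))),
                   class = c("cum_curve", "data.frame"))
  expect_true(is.na(find_endpoint(acc, 15, 90)))

  ## a curve flat after saturation keeps its endpoint before the flat region
  sat <- pmin(cum, 456.9)
  ccs <- structure(data.frame(time_s = tt, value = sat),
                   class = c("cum_curve", "data.frame"))
  eps <- find_endpoint(ccs, 15, 90)
  expect_false(is.na(eps))
  expect_lt(eps, tt[which(sat >= 456.9)[1]])
})

test_that("percentage ceilings follow the native-embolism arithmetic", {
  expect_equal(embolism_end_percent(541, 518, 1100)$raw, 100 * 1059 / 1100)
  expect_identical(embolism_end_percent(541, 518, 1100)$reported, 96)
  expect_identical(embolism_end_percent(541, 457, 1100)$reported, 91)
  expect_equal(embolism_end_percent(0, 200, 200)$raw, 100)
  expect_error(embolism_end_percent(900, 300, 1100), "exceeds")

  ## events confined to the second half: the first bin sits at zero
  cc <- cumulate(c(700, 800, 900), t_range = c(0, 1800))
  vc <- rescale_percentage(cc, 541, 457, 1100)
  expect_equal(max(vc$percent), attr(vc, "end_percent"))
  expect_equal(attr(vc, "end_percent"), 100 * 998 / 1100)
  expect_true(all(diff(vc$percent) >= 0))
  expect_equal(vc$percent[1], 0)
  ## alternative convention starts at the native percentage
  vc2 <- rescale_percentage(cc, 541, 457, 1100, start_at_native = TRUE)
  expect_equal(vc2$percent[1], 100 * 541 / 1100)
})

test_that("segmented regression recovers a planted three-segment model", {
  sm <- list(intercept = -0.2, slopes = c(-1.2, -2, -3.5),
             breakpoints = c(0.5, 1.2), strain_max = 2.3)
  strain <- seq(0.02, 2.3, length.out = 50)
  psi <- xylemAE:::psi_from_strain(sm, strain)
  grid <- seq(0.1, 2.2, by = 0.05)
  fit <- fit_stress_strain(strain, psi, grid = grid)
  expect_equal(fit$breakpoints, c(0.5, 1.2), tolerance = 0.05 + 1e-9)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$slopes, c(-1.2, -2, -3.5), tolerance = 1e-6)

  ## perfectly linear data: degenerate but consistent
  psi_lin <- -0.1 - 1.5 * strain
  fl <- fit_stress_strain(strain, psi_lin, grid = grid)
  expect_lt(fl$rss, 1e-12)
  expect_equal(fl$slopes, rep(-1.5, 3), tolerance = 1e-6)

  expect_error(fit_stress_strain(strain[1:4], psi[1:4]), "at least 6")
})

test_that("noisy segmented fits recover slopes within three simulated standard errors", {
  sm <- list(intercept = -0.2, slopes = c(-1.2, -2, -3.5),
             breakpoints = c(0.5, 1.2), strain_max = 2.3)
  set.seed(43)
  strain <- seq(0.02, 2.3, length.out = 120)
  slopes <- t(replicate(30, {
    psi <- xylemAE:::psi_from_strain(sm, strain) + rnorm(120, 0, 0.08)
    fit_stress_strain(strain, psi, grid = seq(0.1, 2.2, by = 0.02))$slopes
  }))
  ## simulation-estimated standard errors of the two-stage estimator
  se_mean <- apply(slopes, 2, sd) / sqrt(nrow(slopes))
  expect_true(all(abs(colMeans(slopes) - c(-1.2, -2, -3.5)) < 3 * se_mean))
})

test_that("strain-to-psi mapping is continuous and inverts the generator exactly", {
  cfg <- small_config(seed = 44)
  e <- simulate_experiment(cfg)
  strain_at <- approx(e$strain$time_s, e$strain$strain,
                      xout = e$psi_points$time_s)$y
  fit <- fit_stress_strain(strain_at, e$psi_points$psi_mpa,
                           grid = c(0.3, 0.5, 0.8, 1.2, 1.5))
  ## grid contains the true breakpoints and psi points are noise-free
  expect_equal(fit$breakpoints, c(0.5, 1.2), tolerance = 1e-9)
  mapped <- map_time_to_psi(fit, e$strain)
  expect_equal(mapped$psi_mpa,
               xylemAE:::psi_from_strain(cfg$strain_model, e$strain$strain),
               tolerance = 1e-6)
  ## continuity at a breakpoint
  eps <- 1e-9
  expect_equal(predict(fit, 0.5 - eps), predict(fit, 0.5 + eps),
               tolerance = 1e-6)
})

test_that("vulnerability values invert the percentage curve at absolute levels", {
  psi <- seq(0, -6, length.out = 400)
  percent <- 96 * plogis((psi - (-2.3)) / -0.6)
  vc <- data.frame(psi_mpa = psi, percent = percent)
  vv <- vulnerability_values(vc)
  expect_equal(unname(vv["v50"]), -2.3 - 0.6 * qlogis(50 / 96), tolerance = 0.02)
  expect_true(vv["v12"] >= vv["v50"] && vv["v50"] >= vv["v88"])
  expect_true(is.na(vv["v100"]))  # the ceiling is 96

  ## degenerate step curve: all levels collapse onto the step
  step <- data.frame(psi_mpa = psi, percent = ifelse(psi > -3, 0, 90))
  vs <- vulnerability_values(step)
  expect_equal(unname(vs["v12"]), -3, tolerance = 0.05)
  expect_equal(unname(vs["v50"]), -3, tolerance = 0.05)
  expect_equal(unname(vs["v88"]), -3, tolerance = 0.05)

  ## noisy samples of a known monotone curve stay near its true crossings
  set.seed(45)
  noisy <- data.frame(psi_mpa = psi,
                      percent = pmax(pmin(percent + rnorm(400, 0, 1.5), 100), 0))
  vn <- vulnerability_values(noisy)
  expect_equal(unname(vn["v50"]), unname(vv["v50"]), tolerance = 0.05)
})

test_that("curve comparison reports pointwise and v50 differences", {
  psi <- seq(-0.2, -6, length.out = 300)
  pc <- 91 * plogis((psi + 2.34) / -0.5)
  ref <- data.frame(psi_mpa = psi, percent = pc)
  expect_lt(compare_curves(ref, ref)$max_abs_diff, 1e-9)

  offset <- ref; offset$percent <- pmin(offset$percent + 5, 96)
  cmp <- compare_curves(offset, ref)
  mid <- cmp$grid$psi_mpa < -1.5 & cmp$grid$psi_mpa > -4
  expect_equal(mean(cmp$grid$abs_diff[mid]), 5, tolerance = 0.5)

  ## the printed v50 agreement arithmetic
  rel <- relative_v50_difference(-2.30, -2.34)
  expect_equal(rel$raw, 100 * (2.34 - 2.30) / 2.34, tolerance = 1e-12)
  expect_identical(rel$reported, 2)

  far <- data.frame(psi_mpa = seq(-10, -12, length.out = 10), percent = 1:10)
  expect_error(compare_curves(far, ref), "overlap")
})
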