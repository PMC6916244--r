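# Vulnerability-curve construction and comparison: cumulation into 10-min
# bins, moving-window derivatives with the third-derivative endpoint rule,
# native-embolism rescaling, segmented stress-strain mapping of strain to
# xylem water potential, smoothing-spline vulnerability values, and
# absolute-difference curve comparison.

#' Cumulate events (or probabilities) into time bins
#'
#' Forms the running cumulative sum of the event weights and averages it
#' within consecutive bins ("cumulated over the measurement period and
#' averaged over 10 min"). The bin average is taken over a one-minute
#' evaluation grid inside each bin.
#'
#' @param times Event times in seconds.
#' @param weights Per-event weights (1 for counts, posteriors for expected
#'   counts). Default 1.
#' @param bin_minutes Bin width in minutes (default 10).
#' @param t_range Time span covered, `c(start_s, end_s)`; defaults to the
#'   range of `times` and is required when `times` is empty.
#' @return Object of class `cum_curve`: data frame `time_s` (bin centres) and
#'   `value` (non-decreasing), with attribute `bin_minutes`.
#' @export
cumulate <- function(times, weights = NULL, bin_minutes = 10, t_range = NULL) {
  if (is.null(weights)) weights <- rep(1, length(times))
  stopifnot(length(weights) == length(times))
  if (is.null(t_range)) {
    if (!length(times)) stop("empty input needs an explicit t_range", call. = FALSE)
    t_range <- range(times)
  }
  bin_s <- bin_minutes * 60
  n_bins <- max(1L, ceiling((t_range[2] - t_range[1]) / bin_s))
  edges <- t_range[1] + bin_s * (0:n_bins)
  o <- order(times)
  times <- times[o]; weights <- weights[o]
  cum_at <- function(t) {
    idx <- findInterval(t, times)
    c(0, cumsum(weights))[idx + 1L]
  }
  value <- vapply(seq_len(n_bins), function(b) {
    g <- seq(edges[b] + 30, edges[b + 1] - 30, by = 60)
    if (!length(g)) g <- (edges[b] + edges[b + 1]) / 2
    mean(cum_at(g))
  }, numeric(1))
  structure(data.frame(time_s = (edges[-1] + edges[-length(edges)]) / 2,
                       value = value),
            class = c("cum_curve", "data.frame"), bin_minutes = bin_minutes)
}

#' Moving-window derivative of a binned curve
#'
#' Estimates the order-th derivative by repeated windowed least-squares
#' slopes: each pass replaces the series by the slope of a straight-line fit
#' over a centred moving window of width `window_minutes / order`, so that
#' the total support of the order-th derivative spans `window_minutes`.
#' A pass window narrower than 3 bins falls back to the 3 nearest points
#' (a central difference). Points whose window is not fully inside the
#' series get `NA`.
#'
#' @param curve A `cum_curve` (or data frame with `time_s`, `value`).
#' @param order Derivative order (1 or 3).
#' @param window_minutes Total moving-window span in minutes; each of the
#'   `order` passes must cover at least 3 bins.
#' @return Data frame `time_s`, `value` (units value / second^order).
#' @export
moving_derivative <- function(curve, order = 1, window_minutes) {
  stopifnot(order %in% c(1L, 3L) || order >= 1)
  t <- curve$time_s; v <- curve$value
  span <- diff(range(t))
  if (window_minutes * 60 > span)
    stop("window (", window_minutes, " min) longer than the series", call. = FALSE)
  pass_w <- window_minutes * 60 / order
  for (k in seq_len(order)) {
    half <- pass_w / 2
    out <- rep(NA_real_, length(t))
    ok_t <- t[!is.na(v)]
    for (i in seq_along(t)) {
      if (t[i] - half < min(ok_t) - 1e-9 || t[i] + half > max(ok_t) + 1e-9) next
      sel <- which(t >= t[i] - half - 1e-9 & t <= t[i] + half + 1e-9 & !is.na(v))
      if (length(sel) < 3L) {
        ## a window narrower than 3 bins falls back to the 3 nearest points
        cand <- which(!is.na(v))
        sel <- cand[order(abs(t[cand] - t[i]))[seq_len(min(3L, length(cand)))]]
        if (length(sel) < 3L) next
      }
      tt <- t[sel] - t[i]
      out[i] <- sum((tt - mean(tt)) * v[sel]) / sum((tt - mean(tt))^2)
    }
    v <- out
  }
  data.frame(time_s = t, value = v)
}

#' Endpoint of the acoustic curve by the third-derivative rule
#'
#' Locates the time of maximum AE activity (peak of the first derivative of
#' cumulative AE), then searches for the first local maximum of the third
#' derivative occurring after it. When the third derivative is still
#' non-decreasing at the end of the series - the situation where embolism has
#' not finished - the endpoint is undefined and `NA` is returned.
#'
#' @param cumcurve A `cum_curve` of cumulative AE.
#' @param first_window_min Moving window for the first derivative (minutes,
#'   default 15).
#' @param third_window_min Moving window for the third derivative (minutes;
#'   chosen in practice as the time span around peak activity, e.g. 48 h).
#' @return Endpoint time in seconds, or `NA_real_` when undefined.
#' @export
find_endpoint <- function(cumcurve, first_window_min = 15,
                          third_window_min = 2880) {
  d1 <- moving_derivative(cumcurve, 1, first_window_min)
  if (all(is.na(d1$value))) return(NA_real_)
  t_star <- d1$time_s[which.max(d1$value)]
  d3 <- moving_derivative(cumcurve, 3, third_window_min)
  ok <- which(!is.na(d3$value))
  after <- ok[d3$time_s[ok] > t_star]
  if (length(after) < 3L) return(NA_real_)
  for (j in seq(2, length(after) - 1L)) {
    i <- after[j]
    prv <- after[j - 1L]; nxt <- after[j + 1L]
    if (d3$value[i] > d3$value[prv] && d3$value[i] > d3$value[nxt])
      return(d3$time_s[i])
  }
  NA_real_
}

#' Percentage ceiling of a vulnerability curve
#'
#' The end percentage accounts for natively embolized vessels:
#' `100 * (native + detected) / total`. The printed convention rounds to the
#' nearest percent (e.g. 541 native plus 518 detected of 1100 vessels gives
#' 96.27, reported 96).
#'
#' @param native_embolized Vessels already embolized at the start.
#' @param detected_end Events detected by the end of the experiment.
#' @param total_vessels Total vessel count of the cross-section.
#' @return List with `raw` (exact percentage) and `reported` (rounded).
#' @export
embolism_end_percent <- function(native_embolized, detected_end, total_vessels) {
  if (total_vessels <= 0) stop("total_vessels must be positive", call. = FALSE)
  if (native_embolized + detected_end > total_vessels)
    stop("native + detected exceeds total vessels", call. = FALSE)
  raw <- 100 * (native_embolized + detected_end) / total_vessels
  list(raw = raw, reported = round(raw))
}

#' Rescale a cumulative curve to percentage embolism
#'
#' Maps the cumulative curve linearly onto `[0, end_percent]`, where the
#' ceiling includes the native embolism fraction
#' (`100 (native + detected) / total`). The native count raises only the
#' ceiling, not the starting value; set `start_at_native = TRUE` for the
#' alternative convention that offsets the curve by the native percentage.
#'
#' @param cumcurve A `cum_curve` with positive final value.
#' @param native_embolized,detected_end,total_vessels Vessel accounting; see
#'   [embolism_end_percent()]. `detected_end` defaults to the curve's final
#'   value.
#' @param start_at_native Alternative convention (default `FALSE`).
#' @return Object of class `vuln_curve`: data frame `time_s`, `percent`, with
#'   attributes `end_percent` (raw) and `end_percent_reported`.
#' @export
rescale_percentage <- function(cumcurve, native_embolized, detected_end = NULL,
                               total_vessels, start_at_native = FALSE) {
  final <- cumcurve$value[nrow(cumcurve)]
  if (final <= 0) stop("cumulative curve ends at zero", call. = FALSE)
  if (is.null(detected_end)) detected_end <- final
  ep <- embolism_end_percent(native_embolized, detected_end, total_vessels)
  if (start_at_native) {
    lo <- 100 * native_embolized / total_vessels
    percent <- lo + cumcurve$value / final * (ep$raw - lo)
  } else {
    percent <- cumcurve$value / final * ep$raw
  }
  structure(data.frame(time_s = cumcurve$time_s, percent = percent),
            class = c("vuln_curve", "data.frame"),
            end_percent = ep$raw, end_percent_reported = ep$reported)
}

## ---- stress-strain mapping ----------------------------------------------

#' Segmented linear stress-strain regression
#'
#' Fits the three-segment continuous piecewise-linear relation between
#' dendrometer strain (x) and xylem water potential (y) by exhaustive search
#' over candidate breakpoint pairs on a grid of observed strain quantiles,
#' minimizing the total squared psi residual. Candidates leaving fewer than
#' two points in any segment are skipped.
#'
#' @param strain Strain values (micrometre per millimetre).
#' @param psi Matching water potentials (MPa).
#' @param grid Candidate breakpoints; default the 5%--95% strain quantiles in
#'   2.5% steps.
#' @return Object of class `stress_strain`: `breakpoints`, `slopes`,
#'   `intercepts` (per segment), `r_squared` (per segment), `rss`, `fitted`,
#'   `residuals`, and the data.
#' @export
fit_stress_strain <- function(strain, psi, grid = NULL) {
  stopifnot(length(strain) == length(psi))
  if (length(strain) < 6L) stop("need at least 6 points", call. = FALSE)
  if (is.null(grid))
    grid <- unique(as.numeric(quantile(strain, seq(0.05, 0.95, by = 0.025))))
  grid <- sort(grid)
  best <- NULL
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    if (j <= i) next
    b1 <- grid[i]; b2 <- grid[j]
    n_seg <- c(sum(strain <= b1), sum(strain > b1 & strain <= b2), sum(strain > b2))
    if (any(n_seg < 2L)) next
    X <- cbind(strain, pmax(strain - b1, 0), pmax(strain - b2, 0))
    fit <- lm.fit(cbind(1, X), psi)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, b = c(b1, b2), coef = fit$coefficients,
                   fitted = fit$fitted.values, residuals = fit$residuals)
  }
  if (is.null(best)) stop("no valid breakpoint candidate", call. = FALSE)
  cf <- best$coef
  slopes <- c(cf[2], cf[2] + cf[3], cf[2] + cf[3] + cf[4])
  ## per-segment intercepts of the continuous fit
  i1 <- cf[1]
  i2 <- i1 - cf[3] * best$b[1]
  i3 <- i2 - cf[4] * best$b[2]
  seg <- cut(strain, c(-Inf, best$b, Inf), labels = FALSE)
  r2 <- vapply(1:3, function(s) {
    y <- psi[seg == s]
    if (length(y) < 2L || var(y) == 0) return(NA_real_)
    1 - sum(best$residuals[seg == s]^2) / sum((y - mean(y))^2)
  }, numeric(1))
  structure(list(breakpoints = best$b, slopes = unname(slopes),
                 intercepts = unname(c(i1, i2, i3)), r_squared = r2,
                 rss = best$rss, fitted = best$fitted,
                 residuals = best$residuals, strain = strain, psi = psi),
            class = "stress_strain")
}

#' @export
print.stress_strain <- function(x, ...) {
  cat("Segmented stress-strain model (3 linear segments)\n")
  cat(sprintf("  breakpoints: %.3f, %.3f (strain)\n",
              x$breakpoints[1], x$breakpoints[2]))
  for (s in 1:3)
    cat(sprintf("  segment %d: psi = %.3f %+.3f strain  (R^2 %s)\n", s,
                x$intercepts[s], x$slopes[s],
                ifelse(is.na(x$r_squared[s]), "NA", sprintf("%.3f", x$r_squared[s]))))
  invisible(x)
}

#' @rdname fit_stress_strain
#' @param object A `stress_strain` model.
#' @param newdata Strain values at which to evaluate psi.
#' @param ... Unused.
#' @export
predict.stress_strain <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  rng <- range(object$strain)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9))
    warning("strain outside the fitted range; extrapolating linearly")
  b <- object$breakpoints
  object$intercepts[1] + object$slopes[1] * pmin(x, b[1]) +
    object$slopes[2] * pmin(pmax(x - b[1], 0), b[2] - b[1]) +
    object$slopes[3] * pmax(x - b[2], 0)
}

#' @export
plot.stress_strain <- function(x, ...) {
  plot(x$strain, x$psi, xlab = "strain (um/mm)", ylab = "psi (MPa)", ...)
  g <- seq(min(x$strain), max(x$strain), length.out = 200)
  lines(g, predict(x, g), col = 2)
  abline(v = x$breakpoints, lty = 3)
  invisible(x)
}

#' Map a strain trace to a continuous water-potential series
#'
#' @param model A fitted `stress_strain` model.
#' @param strain_trace Data frame with `time_s` and `strain`.
#' @return Data frame `time_s`, `psi_mpa`.
#' @export
map_time_to_psi <- function(model, strain_trace) {
  stopifnot(all(c("time_s", "strain") %in% names(strain_trace)))
  data.frame(time_s = strain_trace$time_s,
             psi_mpa = predict(model, strain_trace$strain))
}

#' Attach a water-potential axis to a vulnerability curve
#'
#' Interpolates the continuous psi series at the curve's bin centres.
#'
#' @param vc A `vuln_curve` (time-based).
#' @param psi_series Data frame `time_s`, `psi_mpa`.
#' @return The curve with an added `psi_mpa` column.
#' @export
vc_attach_psi <- function(vc, psi_series) {
  a <- approx(psi_series$time_s, psi_series$psi_mpa, xout = vc$time_s, rule = 2)
  vc$psi_mpa <- a$y
  vc
}

## ---- vulnerability values and comparison --------------------------------

## Monotone percent-vs-psi function on a fine grid: smoothing spline (GCV)
## through the isotonically corrected curve, then a cumulative-max clamp
## along the dehydration direction.
monotone_percent_fun <- function(psi, percent, n_grid = 2000L) {
  o <- order(-psi)                      # dehydration direction: psi decreasing
  x <- -psi[o]; y <- percent[o]         # x increasing
  iso <- isoreg(x, y)$yf
  grid_x <- seq(min(x), max(x), length.out = n_grid)
  ux <- !duplicated(x)
  if (sum(ux) >= 4) {
    sp <- smooth.spline(x[ux], iso[ux], cv = FALSE)   # GCV stiffness
    pred <- predict(sp, grid_x)$y
  } else {
    pred <- approx(x[ux], iso[ux], xout = grid_x, rule = 2)$y
  }
  pred <- cummax(pmin(pmax(pred, 0), max(iso)))
  list(psi = -grid_x, percent = pred)
}

#' Vulnerability values from a vulnerability curve
#'
#' Fits a smoothing spline (stiffness by generalized cross-validation) to the
#' isotonically corrected percentage-vs-psi curve and returns the water
#' potentials at which it crosses the requested absolute percentage levels
#' (12, 50, 88 and - when reached - 100 percent). Levels above the curve's
#' ceiling are undefined (`NA`), as for a microCT curve that ends below 100%.
#'
#' @param vc A `vuln_curve` with a `psi_mpa` column, or a data frame with
#'   `psi_mpa` and `percent`.
#' @param levels Percentage levels (absolute, not fractions of the ceiling).
#' @return Object of class `vuln_values`: named numeric vector `v12`, `v50`,
#'   `v88`, `v100` (MPa; `NA` when undefined).
#' @export
vulnerability_values <- function(vc, levels = c(12, 50, 88, 100)) {
  stopifnot(all(c("psi_mpa", "percent") %in% names(vc)))
  f <- monotone_percent_fun(vc$psi_mpa, vc$percent)
  out <- vapply(levels, function(lv) {
    if (lv > max(f$percent) + 1e-9) return(NA_real_)
    i <- which(f$percent >= lv)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(f$psi[1])
    ## linear interpolation inside the bracketing grid cell (grid is fine
    ## enough that this equals bisection to well under 0.01 MPa)
    p0 <- f$percent[i - 1L]; p1 <- f$percent[i]
    if (p1 == p0) return(f$psi[i])
    f$psi[i - 1L] + (lv - p0) / (p1 - p0) * (f$psi[i] - f$psi[i - 1L])
  }, numeric(1))
  structure(setNames(out, paste0("v", levels)), class = "vuln_values")
}

#' @export
print.vuln_values <- function(x, ...) {
  cat("Vulnerability values (MPa):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Relative difference of two v50 values
#'
#' `100 * |v50_ref - v50| / |v50_ref|`, with the rounded value as reported in
#' percent.
#'
#' @param v50,v50_ref The two water potentials (MPa).
#' @return List `raw`, `reported`.
#' @export
relative_v50_difference <- function(v50, v50_ref) {
  raw <- 100 * abs(v50_ref - v50) / abs(v50_ref)
  list(raw = raw, reported = round(raw))
}

#' Absolute-difference comparison of two vulnerability curves
#'
#' Interpolates both percentage curves onto a common water-potential grid over
#' the overlapping psi range and reports the pointwise absolute difference,
#' its mean and maximum, and the relative difference of the v50 values.
#'
#' @param vc_a,vc_ref Curves with `psi_mpa` and `percent` (the second is the
#'   reference, e.g. the microCT curve).
#' @param n_grid Grid size.
#' @return Object of class `vc_comparison`: `grid` (data frame `psi_mpa`,
#'   `abs_diff`), `mean_abs_diff`, `max_abs_diff`, `v50`, `v50_ref`,
#'   `v50_rel_diff` (list `raw`, `reported`).
#' @export
compare_curves <- function(vc_a, vc_ref, n_grid = 200L) {
  lo <- max(min(vc_a$psi_mpa), min(vc_ref$psi_mpa))
  hi <- min(max(vc_a$psi_mpa), max(vc_ref$psi_mpa))
  if (lo >= hi) stop("curves do not overlap in psi", call. = FALSE)
  grid <- seq(hi, lo, length.out = n_grid)
  fa <- monotone_percent_fun(vc_a$psi_mpa, vc_a$percent)
  fr <- monotone_percent_fun(vc_ref$psi_mpa, vc_ref$percent)
  pa <- approx(fa$psi, fa$percent, xout = grid, rule = 2)$y
  pr <- approx(fr$psi, fr$percent, xout = grid, rule = 2)$y
  d <- abs(pa - pr)
  va <- vulnerability_values(vc_a)["v50"]
  vr <- vulnerability_values(vc_ref)["v50"]
  structure(list(grid = data.frame(psi_mpa = grid, abs_diff = d),
                 mean_abs_diff = mean(d), max_abs_diff = max(d),
                 v50 = unname(va), v50_ref = unname(vr),
                 v50_rel_diff = relative_v50_difference(unname(va), unname(vr))),
            class = "vc_comparison")
}

#' @export
print.vc_comparison <- function(x, ...) {
  cat("Vulnerability-curve comparison\n")
  cat(sprintf("  mean |diff| %.2f%%, max |diff| %.2f%%\n",
              x$mean_abs_diff, x$max_abs_diff))
  cat(sprintf("  v50 %.2f vs reference %.2f MPa: %.1f%% (reported %d%%)\n",
              x$v50, x$v50_ref, x$v50_rel_diff$raw, x$v50_rel_diff$reported))
  invisible(x)
}

#' Build a vulnerability curve from event times
#'
#' Convenience chain: [cumulate()] then [rescale_percentage()] then
#' [vc_attach_psi()].
#'
#' @param times Event times (seconds).
#' @param weights Optional per-event weights (e.g. posteriors).
#' @param native_embolized,detected_end,total_vessels Vessel accounting.
#' @param psi_series Continuous psi series (`time_s`, `psi_mpa`).
#' @param bin_minutes Bin width (default 10).
#' @param t_range Time span of the measurement.
#' @return A `vuln_curve` with `time_s`, `percent`, `psi_mpa`.
#' @export
vulnerability_curve <- function(times, weights = NULL, native_embolized,
                                detected_end = NULL, total_vessels,
                                psi_series, bin_minutes = 10, t_range = NULL) {
  cc <- cumulate(times, weights, bin_minutes, t_range)
  vc <- rescale_percentage(cc, native_embolized, detected_end, total_vessels)
  vc_attach_psi(vc, psi_series)
}
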