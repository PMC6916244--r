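# microCT processing: projection, crop/denoise, registration, detection.

disc_image <- function(size = 64, cx = 32, cy = 32, r = 10, level = 140, bg = 0) {
  img <- matrix(bg, size, size)
  g <- expand.grid(r = 1:size, c = 1:size)
  hit <- (g$r - cy)^2 + (g$c - cx)^2 <= r^2
  img[cbind(g$r[hit], g$c[hit])] <- level
  img
}

test_that("mid-slice projection is a per-pixel median of the central slices", {
  base <- disc_image()
  stack <- array(rep(base, 50), dim = c(64, 64, 50))
  expect_equal(extract_midslices(stack, 50), base)
  expect_equal(extract_midslices(stack, 1), base)

  ## one slice corrupted with salt noise: the median ignores it
  set.seed(2)
  bad <- stack
  bad[, , 25] <- base + matrix(sample(c(0, 255), 64 * 64, TRUE, c(0.8, 0.2)), 64)
  expect_equal(extract_midslices(bad, 50), base)
  ## direct median oracle on a random stack
  set.seed(3)
  rnd <- array(rnorm(16 * 16 * 7), dim = c(16, 16, 7))
  expect_equal(extract_midslices(rnd, 7), apply(rnd, c(1, 2), median))
  expect_error(extract_midslices(rnd, 9), "slices")
})

test_that("denoise_crop crops to the thresholded foreground and median-filters", {
  img <- disc_image(64, cx = 30, cy = 26, r = 8)
  out <- denoise_crop(img, margin = 2)
  box <- attr(out, "box")
  expect_equal(box, c(26 - 8 - 2, 26 + 8 + 2, 30 - 8 - 2, 30 + 8 + 2))
  ## independent re-implementation: crop then 3x3 median via direct loops
  crop <- img[box[1]:box[2], box[3]:box[4]]
  oracle <- crop
  for (i in seq_len(nrow(crop))) for (j in seq_len(ncol(crop))) {
    ii <- pmin(pmax((i - 1):(i + 1), 1), nrow(crop))
    jj <- pmin(pmax((j - 1):(j + 1), 1), ncol(crop))
    oracle[i, j] <- median(crop[ii, jj][c(1, 2, 3, 4, 5, 6, 7, 8, 9)])
  }
  expect_equal(unclass(out)[, ], oracle, ignore_attr = TRUE)
  expect_error(denoise_crop(matrix(0, 8, 8)), "foreground")
  ## a pre-cropped clean image is unchanged by the crop step
  tight <- denoise_crop(img, margin = 0, filter = FALSE)
  expect_equal(dim(denoise_crop(tight, margin = 0, filter = FALSE)), dim(tight))
})

test_that("registration recovers planted translations", {
  cfg <- image_config(image_noise_sd = 0, image_drift_px = 0)
  ser <- simulate_image_series(cfg, 0L)
  img <- extract_midslices(ser$stacks[[1]], 9)

  reg0 <- register_pair(img, img)
  expect_lt(max(abs(reg0$shift)), 0.1)
  expect_lt(abs(reg0$scale - 1), 0.01)

  moved <- xylemAE:::shift_image(img, 3, -2)
  reg <- register_pair(img, moved)
  expect_lt(abs(reg$shift[1] - 3), 0.25)
  expect_lt(abs(reg$shift[2] + 2), 0.25)
  expect_lte(reg$mse, reg$identity_mse)
})

test_that("registration never reports a residual above the identity residual", {
  cfg <- image_config(image_noise_sd = 0, image_drift_px = 0)
  ser <- simulate_image_series(cfg, 0L)
  img <- extract_midslices(ser$stacks[[1]], 9)
  ## a 1-degree rotation is outside the shift+scale family
  th <- pi / 180
  nr <- nrow(img); cx <- (nr + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nr))
  sr <- cx + cos(th) * (g$r - cx) - sin(th) * (g$c - cx)
  sc <- cx + sin(th) * (g$r - cx) + cos(th) * (g$c - cx)
  rot <- matrix(xylemAE:::bilinear_sample(img, sr, sc), nr, nr)
  reg <- register_pair(img, rot)
  expect_lte(reg$mse, reg$identity_mse)
})

test_that("difference maxima detection obeys the threshold contract", {
  before <- disc_image(128, cx = 60, cy = 80, r = 5, level = 140, bg = 180)
  expect_identical(nrow(detect_embolisms(before, before)), 0L)

  after <- disc_image(128, cx = 60, cy = 80, r = 5, level = 30, bg = 180)
  ev <- detect_embolisms(before, after, maxima_threshold = 30)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$x - 60), 2)
  expect_lt(abs(ev$y - 80), 2)
  expect_equal(ev$peak_difference, 110)

  ## depth 20 below the threshold of 30: nothing
  shallow <- disc_image(128, cx = 60, cy = 80, r = 5, level = 120, bg = 180)
  expect_identical(nrow(detect_embolisms(before, shallow, 30)), 0L)
  expect_error(detect_embolisms(before, matrix(0, 10, 10)), "shape")
})

test_that("detection is translation-equivariant", {
  before <- disc_image(128, cx = 60, cy = 80, r = 5, level = 140, bg = 180)
  after <- disc_image(128, cx = 60, cy = 80, r = 5, level = 30, bg = 180)
  before2 <- disc_image(128, cx = 67, cy = 75, r = 5, level = 140, bg = 180)
  after2 <- disc_image(128, cx = 67, cy = 75, r = 5, level = 30, bg = 180)
  e1 <- detect_embolisms(before, after)
  e2 <- detect_embolisms(before2, after2)
  expect_equal(e2$x - e1$x, 7, tolerance = 1e-6)
  expect_equal(e2$y - e1$y, -5, tolerance = 1e-6)
})

test_that("count_series recovers planted counts under mild noise and drift", {
  cfg <- image_config(seed = 5)      # noise sd 3, drift 1.5 px (defaults)
  ser <- simulate_image_series(cfg, c(3L, 0L, 5L, 1L))
  res <- count_series(ser, n_midslices = 9)
  expect_identical(res$counts, c(3L, 0L, 5L, 1L))
  expect_identical(sum(res$counts), nrow(res$events))

  ## a duplicated stack appended gives a zero count for the new window
  ser2 <- ser
  ser2$stacks <- c(ser$stacks, ser$stacks[length(ser$stacks)])
  res2 <- count_series(ser2, n_midslices = 9)
  expect_identical(res2$counts[5], 0L)
})

test_that("noise-free planted detection has precision and recall exactly one", {
  cfg <- image_config(seed = 6, image_noise_sd = 0, image_drift_px = 0)
  ser <- simulate_image_series(cfg, c(2L, 4L))
  res <- count_series(ser, n_midslices = 9)
  expect_identical(res$counts, c(2L, 4L))
  for (w in 1:2) {
    truth <- ser$coords[ser$coords$window == w, ]
    got <- res$events[res$events$window_index == w, ]
    d <- sqrt(outer(truth$x, got$x, "-")^2 + outer(truth$y, got$y, "-")^2)
    expect_true(all(apply(d, 1, min) <= 2))   # every planted vessel found
    expect_true(all(apply(d, 2, min) <= 2))   # no spurious event
  }
})

test_that("TIFF stacks round-trip through disk at stored precision", {
  cfg <- image_config(seed = 7, image_noise_sd = 0, image_drift_px = 0,
                      image_n_slices = 3L, image_size = 64L,
                      image_n_vessels = 20L)
  ser <- simulate_image_series(cfg, 0L)
  dir <- withr::local_tempdir()
  write_tiff_stack(ser$stacks[[1]], dir)
  back <- read_tiff_stack(dir)
  expect_equal(dim(back), dim(ser$stacks[[1]]))
  expect_lt(max(abs(back - ser$stacks[[1]])), 0.01)
})
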