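# microCT stack processing: mid-slice projection, crop + median denoise,
# rigid+scale registration, difference-image maxima detection, series counting.

#' Median projection of the mid-centred slices
#'
#' Collapses the `n` slices centred on the stack midpoint into a single 2D
#' image by per-pixel median (robust to single-slice artefacts); a mean
#' projection is available by flag.
#'
#' @param stack 3D array `[row, col, slice]` or list of matrices.
#' @param n Number of central slices to pool (default 50).
#' @param method `"median"` (default) or `"mean"`.
#' @return A 2D image matrix.
#' @export
extract_midslices <- function(stack, n = 50, method = c("median", "mean")) {
  method <- match.arg(method)
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3L)
  ns <- dim(stack)[3]
  if (ns < n)
    stop("stack has ", ns, " slices; ", n, " requested", call. = FALSE)
  mid <- (ns + 1) / 2
  sel <- seq(floor(mid - (n - 1) / 2), length.out = n)
  sub <- stack[, , sel, drop = FALSE]
  if (n == 1L) return(sub[, , 1])
  if (method == "mean") return(apply(sub, c(1, 2), mean))
  apply(sub, c(1, 2), median)
}

#' Crop to the cross-section and median-filter
#'
#' Thresholds the image to find the bright cross-section, crops to its
#' bounding box plus a margin, and applies a 3x3 planar median filter. The
#' crop box can be supplied (`box`) so that two images of a pair are cropped
#' identically; it is returned as an attribute.
#'
#' @param image 2D grayscale matrix, foreground brighter than background.
#' @param threshold Foreground threshold; default half the maximum intensity.
#' @param margin Extra pixels kept around the bounding box.
#' @param box Optional precomputed box `c(r0, r1, c0, c1)`.
#' @param filter Apply the median filter (default `TRUE`).
#' @return Cropped, filtered image with attribute `box`.
#' @export
denoise_crop <- function(image, threshold = NULL, margin = 2, box = NULL,
                         filter = TRUE) {
  if (is.null(box)) {
    if (is.null(threshold)) threshold <- max(image) / 2
    fg <- which(image > threshold, arr.ind = TRUE)
    if (nrow(fg) == 0L) stop("empty foreground", call. = FALSE)
    box <- c(max(1L, min(fg[, 1]) - margin), min(nrow(image), max(fg[, 1]) + margin),
             max(1L, min(fg[, 2]) - margin), min(ncol(image), max(fg[, 2]) + margin))
  }
  out <- image[box[1]:box[2], box[3]:box[4], drop = FALSE]
  if (filter) out <- median_filter3(out)
  attr(out, "box") <- box
  out
}

## Mean squared difference between ref and mov warped by (dx, dy, scale),
## evaluated on the valid overlap only.
registration_mse <- function(ref, mov, dx, dy, scale) {
  w <- warp_shift_scale(mov, dx, dy, scale, fill = NA_real_)
  ok <- !is.na(w)
  if (sum(ok) < 0.25 * length(ref)) return(Inf)
  mean((ref[ok] - w[ok])^2)
}

#' Register a moving image onto a reference
#'
#' Estimates the rigid translation plus isotropic scale (about the image
#' centre) that minimises the mean squared intensity difference, by an integer
#' grid search over translations followed by Nelder-Mead refinement. The
#' reported residual never exceeds the identity-transform residual: if the
#' optimiser fails to improve on the identity, the identity is returned with
#' `converged = FALSE`.
#'
#' @param reference_image,moving_image Equal-sized 2D matrices.
#' @param max_shift Grid-search radius in pixels.
#' @return List of class `uct_registration`: `image` (resampled moving image,
#'   `NA` outside the overlap), `shift` `(dx, dy)`, `scale`, `mse`,
#'   `identity_mse`, `converged`.
#' @export
register_pair <- function(reference_image, moving_image, max_shift = 6L) {
  if (!all(dim(reference_image) == dim(moving_image)))
    stop("images must have the same shape", call. = FALSE)
  ref <- reference_image; mov <- moving_image
  id_mse <- mean((ref - mov)^2)
  ## coarse: integer translations
  best <- c(0, 0); best_mse <- id_mse
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    if (dx == 0 && dy == 0) next
    m <- registration_mse(ref, mov, dx, dy, 1)
    if (m < best_mse) { best_mse <- m; best <- c(dx, dy) }
  }
  ## fine: continuous shift + log-scale
  obj <- function(p) registration_mse(ref, mov, p[1], p[2], exp(p[3]))
  fit <- try(optim(c(best, 0), obj, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-10)), silent = TRUE)
  if (!inherits(fit, "try-error") && fit$value <= best_mse) {
    par <- fit$par; mse <- fit$value
  } else {
    par <- c(best, 0); mse <- best_mse
  }
  converged <- TRUE
  if (mse > id_mse) {  # contract floor: never worse than doing nothing
    par <- c(0, 0, 0); mse <- id_mse; converged <- FALSE
    warning("registration failed to improve on identity; returning identity")
  }
  out <- warp_shift_scale(mov, par[1], par[2], exp(par[3]), fill = NA_real_)
  structure(list(image = out, shift = c(dx = par[1], dy = par[2]),
                 scale = exp(par[3]), mse = mse, identity_mse = id_mse,
                 converged = converged),
            class = "uct_registration")
}

#' @export
print.uct_registration <- function(x, ...) {
  cat(sprintf("registration: shift (%.2f, %.2f) px, scale %.4f, MSE %.3g (identity %.3g)\n",
              x$shift[1], x$shift[2], x$scale, x$mse, x$identity_mse))
  invisible(x)
}

#' Detect embolism events between two registered images
#'
#' Computes the difference `before - after` (grey-to-black vessel transitions
#' become positive peaks) and reports one event per connected region of
#' difference at least `maxima_threshold` grey values above the
#' zero-difference baseline (8-connectivity, the flood-merge behaviour of
#' interactive maxima finders), located at the region's intensity-weighted
#' centroid. Events closer than `min_separation` pixels are suppressed
#' greedily, strongest first.
#'
#' @param image_before,image_after Registered, equal-sized images. `NA`
#'   pixels (outside the registration overlap) are ignored.
#' @param maxima_threshold Minimum peak height above baseline (grey values).
#' @param min_separation Minimum distance between accepted peaks (pixels).
#' @return Data frame of class `embolism_events`: `x`, `y` (pixel coordinates,
#'   column/row), `peak_difference`.
#' @export
detect_embolisms <- function(image_before, image_after, maxima_threshold = 30,
                             min_separation = 3) {
  if (!all(dim(image_before) == dim(image_after)))
    stop("images must have the same shape", call. = FALSE)
  d <- image_before - image_after
  d[is.na(d)] <- 0
  nr <- nrow(d)
  cand <- which(d >= maxima_threshold, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), peak_difference = numeric(0))
  class(empty) <- c("embolism_events", "data.frame")
  if (nrow(cand) == 0L) return(empty)
  comp <- label_components(cand, nr)
  peaks <- do.call(rbind, lapply(split(seq_len(nrow(cand)), comp), function(ii) {
    w <- d[cand[ii, , drop = FALSE]]
    data.frame(x = sum(cand[ii, 2] * w) / sum(w),
               y = sum(cand[ii, 1] * w) / sum(w),
               peak_difference = max(w))
  }))
  ## greedy min-separation suppression, strongest first
  peaks <- peaks[order(-peaks$peak_difference), , drop = FALSE]
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- which(keep)
    dist2 <- (peaks$x[sel] - peaks$x[i])^2 + (peaks$y[sel] - peaks$y[i])^2
    if (all(dist2 >= min_separation^2)) keep[i] <- TRUE
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("embolism_events", "data.frame")
  out
}

## Label 8-connected components among candidate pixels (rows of arr.ind).
label_components <- function(cand, nr) {
  n <- nrow(cand)
  key <- (cand[, 2] - 1) * nr + cand[, 1]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        k <- as.character((cand[j, 2] + dc - 1) * nr + cand[j, 1] + dr)
        hit <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && comp[hit] == 0L) {
          comp[hit] <- cur
          queue <- c(queue, hit)
        }
      }
    }
  }
  comp
}

#' Count embolism events across a microCT series
#'
#' Runs the full per-pair chain on consecutive stacks: mid-slice median
#' projection, joint crop (box from the earlier image of each pair) with
#' median filtering, rigid+scale registration, difference and maxima
#' detection. Event coordinates are reported in the uncropped frame of the
#' earlier stack of each pair.
#'
#' @param stacks List of 3D slice arrays (or a `uct_series`).
#' @param maxima_threshold,min_separation Passed to [detect_embolisms()].
#' @param n_midslices,projection Passed to [extract_midslices()].
#' @param register Register each pair before differencing (default `TRUE`).
#' @return List of class `uct_counts`: `counts` (per inter-stack window),
#'   `events` (data frame `window_index`, `x`, `y`, `peak_difference`),
#'   `registrations`.
#' @export
count_series <- function(stacks, maxima_threshold = 30, min_separation = 3,
                         n_midslices = NULL, projection = "median",
                         register = TRUE) {
  if (inherits(stacks, "uct_series")) stacks <- stacks$stacks
  if (length(stacks) < 2L) stop("need at least 2 stacks", call. = FALSE)
  proj <- lapply(stacks, function(s) {
    s <- if (is.list(s)) simplify2array(s) else s
    n <- if (is.null(n_midslices)) dim(s)[3] else n_midslices
    extract_midslices(s, n = n, method = projection)
  })
  events <- list(); counts <- integer(length(stacks) - 1L)
  regs <- list()
  for (w in seq_len(length(stacks) - 1L)) {
    before <- proj[[w]]; after <- proj[[w + 1L]]
    cb <- denoise_crop(before)
    ca <- denoise_crop(after, box = attr(cb, "box"))
    if (register) {
      reg <- register_pair(cb, ca)
      after_c <- reg$image
      regs[[w]] <- reg
    } else after_c <- ca
    ev <- detect_embolisms(cb, after_c, maxima_threshold, min_separation)
    if (nrow(ev)) {
      box <- attr(cb, "box")
      ev$x <- ev$x + box[3] - 1
      ev$y <- ev$y + box[1] - 1
      ev <- data.frame(window_index = w, ev)
      events[[length(events) + 1L]] <- ev
    }
    counts[w] <- nrow(ev)
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(window_index = integer(0), x = numeric(0), y = numeric(0),
                  peak_difference = numeric(0))
  structure(list(counts = counts, events = events, registrations = regs),
            class = "uct_counts")
}

#' @export
print.uct_counts <- function(x, ...) {
  cat(sprintf("microCT series: %d windows, %d embolism events (counts: %s)\n",
              length(x$counts), sum(x$counts),
              paste(x$counts, collapse = ", ")))
  invisible(x)
}

#' Write a microCT stack as numbered TIFF slices
#'
#' Grey values are scaled from `[0, 255]` to `[0, 1]` and stored at 16 bit.
#'
#' @param stack 3D array `[row, col, slice]`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @export
write_tiff_stack <- function(stack, dir, prefix = "slice") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ns <- dim(stack)[3]
  for (k in seq_len(ns)) {
    img <- pmin(pmax(stack[, , k] / 255, 0), 1)
    tiff::writeTIFF(img, file.path(dir, sprintf("%s_%04d.tif", prefix, k)),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}

#' Read a directory of numbered TIFF slices into a stack
#'
#' @param dir Directory containing `*.tif` files (lexicographic slice order).
#' @return 3D array `[row, col, slice]` in `[0, 255]` grey values.
#' @export
read_tiff_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(files)) stop("no TIFF slices in ", dir, call. = FALSE)
  slices <- lapply(files, function(f) tiff::readTIFF(f) * 255)
  simplify2array(slices)
}
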