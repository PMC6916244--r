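# Internal helpers shared across modules.

## Derive k reproducible child seeds from one master seed so independent
## generator components (counts, features, images, ...) do not share streams.
child_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)

is_square_spd <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  !inherits(try(chol(m), silent = TRUE), "try-error")
}

## Bilinear sampling of matrix `img` at fractional (row, col) coordinates.
## Out-of-range samples return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    val[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i11] * fr[ok] * fc[ok]
  }
  val[!ok] <- fill
  val
}

## Resample an image under a content shift (dx, dy) in (col, row) pixels and an
## isotropic scale about the image centre: content that sat at p in the
## reference appears at centre + s * (p - centre) + d in the returned image's
## source. warp(img, d, s) undoes that displacement.
warp_shift_scale <- function(img, dx, dy, scale = 1, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  sr <- cy + scale * (g$r - cy) + dy
  sc <- cx + scale * (g$c - cx) + dx
  out <- bilinear_sample(img, sr, sc, fill = if (is.na(fill)) 0 else fill)
  if (is.na(fill)) out[sr < 1 | sr > nr | sc < 1 | sc > nc] <- NA_real_
  matrix(out, nr, nc)
}

## Shift image content by (dx, dy): a feature at (x, y) moves to (x+dx, y+dy).
shift_image <- function(img, dx, dy, fill = 0) {
  warp_shift_scale(img, dx = -dx, dy = -dy, scale = 1, fill = fill)
}

## 3x3 planar median filter with edge replication.
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  nbr <- matrix(0, nr * nc, 9L)
  k <- 0L
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1L
    nbr[, k] <- as.vector(pad[dr + seq_len(nr), dc + seq_len(nc)])
  }
  ## median of 9 = 5th order statistic, via per-row partial sort
  matrix(apply(nbr, 1L, function(v) sort.int(v, partial = 5L)[5L]), nr, nc)
}
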