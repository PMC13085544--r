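# Shared raster helpers. Images are plain numeric arrays in [0, 1]:
# grayscale = matrix (rows = y, cols = x), RGB = h x w x 3 array.
# 8-bit files round-trip exactly because slices are quantized to k/255.

#' Convert an RGB raster to grayscale
#'
#' Uses the fixed luminance convention 0.299 R + 0.587 G + 0.114 B. All
#' registration metrics and stack-coherence metrics in the package operate on
#' this grayscale, also for RGB inputs.
#'
#' @param img h x w x 3 array in \[0, 1\], or a matrix (returned unchanged).
#' @return numeric matrix in \[0, 1\].
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Vectorized bilinear lookup of matrix `m` at fractional pixel coordinates
# (x = column, y = row, 1-indexed). Out-of-frame coordinates return `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  ok <- x >= 1 & x <= w & y >= 1 & y <= h
  bad <- !ok
  if (any(bad)) { x[bad] <- 1; y[bad] <- 1 }
  # nudge off the top edge so x0 + 1 stays in range
  x <- pmin(x, w - 1e-7); y <- pmin(y, h - 1e-7)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v <- (1 - fx) * (1 - fy) * m[i00] + fx * (1 - fy) * m[i00 + h] +
       (1 - fx) * fy * m[i00 + 1] + fx * fy * m[i00 + h + 1]
  v[bad] <- fill
  v
}

# Warp an image by a rigid2d: output(p) = input(t^{-1}(p)), bilinear, so the
# image content is moved by `t`. Works for matrices and h x w x 3 arrays;
# `fill` recycles across channels.
warp_image <- function(img, t, fill = 0) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ti <- rigid2d_invert(t)
  grid <- cbind(x = rep(seq_len(w), each = h), y = rep(seq_len(h), times = w))
  src <- rigid2d_apply(ti, grid)
  if (is.matrix(img)) {
    return(matrix(bilinear_sample(img, src[, 1], src[, 2], fill = fill[1]), h, w))
  }
  fill <- rep(fill, length.out = d[3])
  out <- array(0, d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- matrix(bilinear_sample(img[, , ch], src[, 1], src[, 2],
                                          fill = fill[ch]), h, w)
  out
}

# 2x block-mean downsampling (truncates odd trailing row/col); used by the
# registration pyramid.
downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
          m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)])
}

# Quantize to 8-bit levels k/255 so PNG/TIFF round trips are bit-exact.
quantize8 <- function(img) {
  img[img < 0] <- 0; img[img > 1] <- 1
  round(img * 255) / 255
}

#' Geometric center of an image
#'
#' The rotation center used by default throughout the package:
#' `((w + 1) / 2, (h + 1) / 2)` in 1-indexed pixel coordinates.
#'
#' @param img_or_dim an image (matrix/array) or a dimension vector `c(h, w)`.
#' @return numeric `(cx, cy)`.
#' @export
image_center <- function(img_or_dim) {
  d <- if (is.numeric(img_or_dim) && length(img_or_dim) <= 3L) img_or_dim
       else dim(img_or_dim)
  c((d[2] + 1) / 2, (d[1] + 1) / 2)
}
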