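# Geometric resampling primitives shared by scan conversion, crop/resize,
# rotation/shift, and depth/convexity change. All bilinear, constant-0 fill.

#' Sample a matrix at fractional coordinates by bilinear interpolation
#'
#' @param img numeric matrix.
#' @param rows,cols numeric vectors of equal length: 0-based fractional
#'   (row, col) source coordinates. Points outside the matrix evaluate to
#'   `fill`.
#' @param fill value used outside the source extent (default 0).
#' @return numeric vector of interpolated values, same length as `rows`.
#' @export
bilinear_sample <- function(img, rows, cols, fill = 0) {
  .bilinear_core(img, as.numeric(rows), as.numeric(cols), fill)
}

#' Resize a matrix with bilinear interpolation
#'
#' Pixel centres are mapped so the corner pixels of source and target align.
#'
#' @param img numeric matrix.
#' @param out_rows,out_cols target dimensions.
#' @return resized numeric matrix.
#' @export
resize_bilinear <- function(img, out_rows, out_cols) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- if (out_rows == 1) 0 else seq(0, nr - 1, length.out = out_rows)
  cc <- if (out_cols == 1) 0 else seq(0, nc - 1, length.out = out_cols)
  grid_r <- rep(rr, times = out_cols)
  grid_c <- rep(cc, each = out_rows)
  matrix(bilinear_sample(img, grid_r, grid_c), nrow = out_rows, ncol = out_cols)
}

#' Separable Gaussian convolution with reflective boundary
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; kernel radius is
#'   `ceiling(3 * sigma)`.
#' @return filtered matrix, same dimensions.
#' @export
gaussian_filter <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- as.integer(ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- apply_conv_1d(img, k, rad)          # along rows (vertical)
  t(apply_conv_1d(t(img), k, rad))           # along cols (horizontal)
}

# convolve each column of img with kernel k (radius rad), reflecting at edges
apply_conv_1d <- function(img, k, rad) {
  nr <- nrow(img)
  idx <- seq_len(nr)
  out <- matrix(0, nr, ncol(img))
  for (o in -rad:rad) {
    j <- idx + o
    # reflect indices about the edges (symmetric padding)
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > nr, 2 * nr - j, j)
    j <- pmin(pmax(j, 1L), nr)   # guard tiny images against double reflection
    out <- out + k[o + rad + 1] * img[j, , drop = FALSE]
  }
  out
}
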