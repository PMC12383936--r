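#' Construct an ultrasound image object
#'
#' An `us_image` bundles a grayscale pixel grid (stored as doubles in
#' \[0, 1\]), a binary field-of-view (FOV) mask of the same shape, an optional
#' [fov_geometry()] descriptor, and bookkeeping labels used by the dataset
#' splitters.
#'
#' @param pixels numeric matrix in \[0, 1\] (values are clipped), or an
#'   integer matrix in \[0, 255\] which is rescaled.
#' @param mask binary matrix (0/1) of the same dimensions, 1 inside the FOV.
#'   Defaults to all ones.
#' @param geometry an [fov_geometry()] object or `NULL`.
#' @param patient_id opaque string used for grouped splitting.
#' @param label optional class label (phantom ground truth).
#' @return an object of class `us_image`.
#' @export
#' @examples
#' img <- us_image(matrix(runif(64), 8, 8))
#' dim(img$pixels)
us_image <- function(pixels, mask = NULL, geometry = NULL,
                     patient_id = NA_character_, label = NA_character_) {
  stopifnot(is.matrix(pixels))
  d <- dim(pixels)
  p <- as.numeric(pixels)
  if (length(p) && max(p, na.rm = TRUE) > 1) p <- p / 255
  pixels <- matrix(pmin(pmax(p, 0), 1), d[1], d[2])
  if (is.null(mask)) mask <- matrix(1, nrow(pixels), ncol(pixels))
  if (!all(dim(mask) == dim(pixels)))
    stop("`mask` and `pixels` must have identical dimensions", call. = FALSE)
  mask <- (mask > 0.5) * 1
  structure(
    list(pixels = pixels, mask = mask, geometry = geometry,
         patient_id = patient_id, label = label),
    class = "us_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.us_image <- function(x, ...) {
  g <- if (is.null(x$geometry)) "none" else x$geometry$kind
  cat(sprintf("<us_image %dx%d, FOV %.1f%%, geometry: %s%s%s>\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$mask), g,
              if (!is.na(x$patient_id)) paste0(", patient ", x$patient_id) else "",
              if (!is.na(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

# quantise [0,1] doubles to the 8-bit grid, round half up
quantize8 <- function(x) floor(pmin(pmax(x, 0), 1) * 255 + 0.5) / 255

#' Read a grayscale PNG (and optional mask) as an ultrasound image
#'
#' Multichannel PNGs are collapsed by channel mean. Mask PNGs use
#' \{0, 255\} mapped to \{0, 1\} (any value > 127 counts as inside).
#'
#' @param path path to an 8-bit PNG image.
#' @param mask_path optional path to a binary mask PNG.
#' @inheritParams us_image
#' @return an `us_image`.
#' @export
read_us_image <- function(path, mask_path = NULL,
                          patient_id = NA_character_, label = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , seq_len(min(3, dim(px)[3])), drop = FALSE],
                                        c(1, 2), mean)
  mask <- NULL
  if (!is.null(mask_path)) {
    mk <- png::readPNG(mask_path)
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    mask <- (mk > 0.5) * 1
  }
  us_image(px, mask, patient_id = patient_id, label = label)
}

#' Write an ultrasound image (and optionally its mask) to 8-bit PNG
#'
#' Pixels are quantised to the 8-bit grid with round-half-up.
#'
#' @param image an `us_image`.
#' @param path output PNG path.
#' @param mask_path optional output path for the binary mask (written as
#'   \{0, 255\}).
#' @return `path`, invisibly.
#' @export
write_us_image <- function(image, path, mask_path = NULL) {
  png::writePNG(quantize8(image$pixels), path)
  if (!is.null(mask_path)) png::writePNG(image$mask, mask_path)
  invisible(path)
}
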