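# StandardAug operators (A00-A05): the photographic augmentation family used
# as the baseline positive-pair pipeline. Every operator works on [0,1]
# pixels, re-zeroes content outside the FOV mask, and separates "draw" (all
# randomness) from "apply" (deterministic given the draw) so that logged
# draws replay bit-exactly.

mask_zero <- function(image) {
  image$pixels <- image$pixels * image$mask
  image
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Crop-and-resize parameters
#'
#' @param c_min minimum crop area fraction (default 0.08).
#' @param c_max maximum crop area fraction (default 1).
#' @param aspect_range width/height aspect-ratio bounds, sampled
#'   log-uniformly.
#' @param out_size output `(rows, cols)` after resizing.
#' @return a list of class `crop_params`.
#' @export
crop_params <- function(c_min = 0.08, c_max = 1.0,
                        aspect_range = c(3 / 4, 4 / 3),
                        out_size = c(128, 128)) {
  stopifnot(c_min > 0, c_min <= c_max, c_max <= 1,
            aspect_range[1] <= 1, aspect_range[2] >= 1)
  structure(list(c_min = c_min, c_max = c_max, aspect_range = aspect_range,
                 out_size = out_size), class = "crop_params")
}

#' Sample a crop window
#'
#' Draws the random window used by [crop_and_resize()]: area fraction
#' uniform in `[c_min, c_max]`, log-uniform aspect ratio, with up to 10
#' rejection attempts before the centred fallback window. Uses the current
#' RNG state.
#'
#' @param image an [us_image()].
#' @param cfg a [crop_params()].
#' @return a list with `r0`, `c0` (0-based top-left), `h`, `w` and the
#'   realised `area_frac`.
#' @export
draw_crop <- function(image, cfg) {
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  area <- h * w
  for (i in seq_len(10)) {
    frac <- runif(1, cfg$c_min, cfg$c_max)
    ar <- exp(runif(1, log(cfg$aspect_range[1]), log(cfg$aspect_range[2])))
    # ceiling keeps the realised window area at or above the sampled
    # fraction, preserving the [c_min, c_max] area contract
    ch <- ceiling(sqrt(area * frac / ar))
    cw <- ceiling(sqrt(area * frac * ar))
    if (ch >= 1 && cw >= 1 && ch <= h && cw <= w) {
      r0 <- floor(runif(1, 0, h - ch + 1))
      c0 <- floor(runif(1, 0, w - cw + 1))
      return(list(r0 = min(r0, h - ch), c0 = min(c0, w - cw),
                  h = ch, w = cw, area_frac = ch * cw / area))
    }
  }
  # fallback: centred crop at sqrt(c_min) linear scale, image's own aspect
  ch <- max(1, ceiling(h * sqrt(cfg$c_min)))
  cw <- max(1, ceiling(w * sqrt(cfg$c_min)))
  list(r0 = floor((h - ch) / 2), c0 = floor((w - cw) / 2),
       h = ch, w = cw, area_frac = ch * cw / area)
}

apply_crop <- function(image, params, cfg) {
  rs <- params$r0 + seq_len(params$h)
  cs <- params$c0 + seq_len(params$w)
  px <- resize_bilinear(image$pixels[rs, cs, drop = FALSE],
                        cfg$out_size[1], cfg$out_size[2])
  mk <- resize_bilinear(image$mask[rs, cs, drop = FALSE],
                        cfg$out_size[1], cfg$out_size[2])
  image$pixels <- clip01(px)
  image$mask <- (mk >= 0.5) * 1
  image$geometry <- NULL   # the warped FOV no longer matches a parametric shape
  mask_zero(image)
}

#' Random crop and resize (A00)
#'
#' Samples a window with area fraction uniform in `[c_min, c_max]` and a
#' log-uniform aspect ratio, rejection-sampling up to 10 windows that fit
#' the frame (then falling back to a centred crop at `sqrt(c_min)` linear
#' scale), and resizes it to `out_size`. The mask is cropped and resized
#' identically and re-binarised at 0.5.
#'
#' @param image an [us_image()] (at least 8x8).
#' @param params a [crop_params()].
#' @param draw optional previously drawn parameter list (for replay).
#' @return the transformed `us_image`.
#' @export
crop_and_resize <- function(image, params = crop_params(), draw = NULL) {
  if (any(dim(image$pixels) < 8)) stop("image must be at least 8x8", call. = FALSE)
  if (is.null(draw)) draw <- draw_crop(image, params)
  apply_crop(image, draw, params)
}

#' Horizontal reflection (A01 / B10)
#'
#' Column `j` maps to column `cols - 1 - j` in pixels and mask; a fan
#' geometry's apex column is mirrored (the sector is symmetric about the
#' vertical through its apex).
#'
#' @param image an [us_image()].
#' @return the reflected `us_image`.
#' @export
horizontal_reflect <- function(image) {
  nc <- ncol(image$pixels)
  image$pixels <- image$pixels[, nc:1, drop = FALSE]
  image$mask <- image$mask[, nc:1, drop = FALSE]
  if (!is.null(image$geometry))
    image$geometry$apex[2] <- (nc - 1) - image$geometry$apex[2]
  image
}

draw_jitter <- function(image, cfg) {
  list(order = sample(4),
       brightness = runif(1, max(0, 1 - cfg$brightness), 1 + cfg$brightness),
       contrast = runif(1, max(0, 1 - cfg$contrast), 1 + cfg$contrast),
       saturation = runif(1, max(0, 1 - cfg$saturation), 1 + cfg$saturation),
       hue = runif(1, -cfg$hue, cfg$hue))
}

apply_jitter <- function(image, params, cfg) {
  inm <- image$mask > 0
  x <- image$pixels
  for (op in params$order) {
    if (op == 1) {                     # brightness
      x[inm] <- x[inm] * params$brightness
    } else if (op == 2) {              # contrast about the in-FOV mean
      m <- mean(x[inm])
      x[inm] <- m + (x[inm] - m) * params$contrast
    }
    # saturation (3) and hue (4) collapse to the identity on single-channel
    # input: replicating to RGB, scaling chroma and rotating hue, then
    # taking the channel mean returns the original gray value.
    x <- clip01(x)
  }
  image$pixels <- x
  mask_zero(image)
}

#' Colour jitter (A02)
#'
#' Applies, in random order, multiplicative brightness in
#' `[1 - b, 1 + b]`, contrast scaling about the in-FOV mean in
#' `[1 - c, 1 + c]`, and saturation/hue perturbations (exact no-ops for
#' grayscale input after channel collapse), clipping to \[0, 1\] after each
#' step.
#'
#' @param image an [us_image()].
#' @param strengths numeric `(brightness, contrast, saturation, hue)`
#'   maximum deviations.
#' @param draw optional previously drawn parameter list.
#' @return the jittered `us_image`.
#' @export
colour_jitter <- function(image, strengths = c(0.8, 0.8, 0.8, 0.2), draw = NULL) {
  cfg <- list(brightness = strengths[1], contrast = strengths[2],
              saturation = strengths[3], hue = strengths[4])
  if (is.null(draw)) draw <- draw_jitter(image, cfg)
  apply_jitter(image, draw, cfg)
}

#' Conversion to grayscale (A03)
#'
#' The package stores single-channel images, so this is the identity (it is
#' still logged when applied in a pipeline); multichannel arrays collapse by
#' channel mean in [read_us_image()].
#'
#' @param image an [us_image()].
#' @return `image`, unchanged.
#' @export
to_grayscale <- function(image) image

#' Gaussian blur (A04)
#'
#' Convolution with an isotropic Gaussian kernel (radius `ceiling(3*sigma)`,
#' reflective boundary), sigma drawn uniformly from `sigma_range`. The mask
#' is untouched; blurred content is re-zeroed outside it.
#'
#' @param image an [us_image()].
#' @param sigma_range range to draw sigma from (pixels).
#' @param draw optional previously drawn parameter list (`list(sigma=)`).
#' @return the blurred `us_image`.
#' @export
gaussian_blur <- function(image, sigma_range = c(0.1, 2.0), draw = NULL) {
  if (is.null(draw)) draw <- list(sigma = runif(1, sigma_range[1], sigma_range[2]))
  image$pixels <- clip01(gaussian_filter(image$pixels, draw$sigma))
  mask_zero(image)
}

#' Solarization (A05)
#'
#' Pixels at or above `threshold` are replaced by their negative
#' `1 - pixel`; others are unchanged. Applied inside the FOV only.
#'
#' @param image an [us_image()].
#' @param threshold intensity threshold in \[0, 1\] (values > 1 make this
#'   the identity).
#' @return the solarized `us_image`.
#' @export
solarize <- function(image, threshold = 0.5) {
  inm <- image$mask > 0
  x <- image$pixels
  sel <- inm & x >= threshold
  x[sel] <- 1 - x[sel]
  image$pixels <- x
  mask_zero(image)
}
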