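# Ultrasound-specific operators (B00-B11): FOV-aware geometric changes,
# intensity remappings, and the three noise families prevalent in B-mode
# imaging. Heavy random fields are parameterised by a drawn sub-seed so a
# logged draw replays bit-exactly without storing the field.

rewrap <- function(image, pixels, mask = image$mask, geometry = image$geometry) {
  image$pixels <- clip01(pixels)
  image$mask <- mask
  image$geometry <- geometry
  mask_zero(image)
}

#' Noise parameters for the ultrasound noise operators
#'
#' @param speckle_sigma standard deviation of the (smoothed) speckle field.
#' @param gauss_sigma standard deviation of per-pixel multiplicative
#'   Gaussian noise.
#' @param sp_rate fraction of in-FOV pixels hit by salt-and-pepper
#'   replacement (at most 0.1).
#' @return a list of class `noise_params`.
#' @export
noise_params <- function(speckle_sigma = 0.25, gauss_sigma = 0.1, sp_rate = 0.01) {
  stopifnot(speckle_sigma >= 0, gauss_sigma >= 0, sp_rate >= 0, sp_rate <= 0.1)
  structure(list(speckle_sigma = speckle_sigma, gauss_sigma = gauss_sigma,
                 sp_rate = sp_rate), class = "noise_params")
}

draw_subseed <- function() sample.int(2147483646L, 1)

#' Probe type change (B00)
#'
#' Converts a linear field of view to a curvilinear one (treating the
#' in-FOV rectangle as beam space and scan-converting it to a fan with a
#' freshly drawn angular half-width), and converts curvilinear or phased
#' fields of view to linear ones (inverse scan conversion, resized to the
#' frame). The stored geometry is updated to the new kind.
#'
#' @param image an [us_image()] carrying a [fov_geometry()].
#' @param theta0_range range for the drawn fan half-width (radians), used
#'   for linear inputs.
#' @param r_min_frac inner-radius fraction of the generated fan.
#' @param draw optional previously drawn parameter list.
#' @return the converted `us_image`.
#' @export
probe_type_change <- function(image, theta0_range = c(0.3, 0.7),
                              r_min_frac = 0.15, draw = NULL) {
  g <- image$geometry
  if (is.null(g)) stop("probe_type_change requires FOV geometry", call. = FALSE)
  if (is.null(draw)) draw <- list(theta0 = runif(1, theta0_range[1], theta0_range[2]))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  if (g$kind == "linear") {
    beam <- crop_to_fov(image)$pixels
    rho <- r_min_frac
    r_max <- min((h - 1) / (1 - rho), ((w - 1) / 2) / sin(draw$theta0))
    g2 <- fov_geometry("curvilinear",
                       apex = c(-rho * r_max, (w - 1) / 2),
                       theta0 = draw$theta0,
                       r_min = rho * r_max, r_max = r_max)
    out <- scan_convert(beam, g2, shape = c(h, w))
    out$patient_id <- image$patient_id; out$label <- image$label
    out
  } else {
    beam <- inverse_scan_convert(image)
    px <- resize_bilinear(beam, h, w)
    g2 <- fov_geometry("linear", apex = c(0, (w - 1) / 2), theta0 = 0,
                       r_min = 0, r_max = h - 1, width = w - 1)
    rewrap(image, px, mask = matrix(1, h, w), geometry = g2)
  }
}

#' Convexity change (B01)
#'
#' Resamples a fan-shaped image onto a geometry whose angular half-width is
#' multiplied by a drawn factor (clamped to `theta0_bounds`), changing the
#' lateral separation of the fan's bottom corners. Linear inputs are a
#' logged no-op.
#'
#' @param image an [us_image()] with fan geometry.
#' @param m_range range of the half-width multiplier.
#' @param theta0_bounds clamp for the resulting half-width (radians).
#' @param draw optional previously drawn parameter list.
#' @return the resampled `us_image`.
#' @export
convexity_change <- function(image, m_range = c(0.7, 1.3),
                             theta0_bounds = c(0.1, 1.2), draw = NULL) {
  if (is.null(draw)) draw <- list(m = runif(1, m_range[1], m_range[2]))
  g <- image$geometry
  if (is.null(g) || g$kind == "linear") {
    if (getOption("lusaug.verbose", FALSE))
      message("convexity_change: linear FOV, no-op")
    return(image)
  }
  th2 <- min(max(draw$m * g$theta0, theta0_bounds[1]), theta0_bounds[2])
  g2 <- g; g2$theta0 <- th2
  shape <- dim(image$pixels)
  mask2 <- render_fov_mask(g2, shape)
  out <- matrix(0, shape[1], shape[2])
  idx <- which(mask2 > 0)
  row <- (idx - 1) %% shape[1]; col <- (idx - 1) %/% shape[1]
  dr <- row - g$apex[1]; dc <- col - g$apex[2]
  r <- sqrt(dr^2 + dc^2)
  th <- atan2(dc, dr) * (g$theta0 / th2)    # compress/stretch the angle
  out[idx] <- bilinear_sample(image$pixels,
                              g$apex[1] + r * cos(th),
                              g$apex[2] + r * sin(th))
  rewrap(image, out, mask = mask2, geometry = g2)
}

#' Wavelet-shrinkage denoising (B02)
#'
#' Multi-level orthogonal wavelet decomposition with the Birge-Massart
#' retention rule (see [bm_threshold()]): at detail level `j` (1 =
#' coarsest) only the `m / (j + 1)^alpha` largest-magnitude detail
#' coefficients are kept, the rest are zeroed, and the image is
#' reconstructed. Deterministic given its configuration.
#'
#' @param image an [us_image()] with sides at least `2^levels`.
#' @param levels decomposition depth (default 3).
#' @param alpha sparsity exponent (default 3; larger discards more).
#' @param m retention base; default = size of the coarsest approximation
#'   band.
#' @return the denoised `us_image`.
#' @export
wavelet_denoise <- function(image, levels = 3, alpha = 3, m = NULL) {
  d <- dim(image$pixels)
  if (any(d < 2^levels))
    stop("image sides must be at least 2^levels", call. = FALSE)
  blk <- 2^levels
  pr <- ceiling(d[1] / blk) * blk - d[1]
  pc <- ceiling(d[2] / blk) * blk - d[2]
  x <- image$pixels
  if (pr > 0) x <- rbind(x, x[rep(d[1], pr), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, rep(d[2], pc), drop = FALSE])
  w <- bm_threshold(dwt2(x, levels), alpha = alpha, m = m)
  y <- idwt2(w)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  rewrap(image, y)
}

#' Contrast-limited adaptive histogram equalization (B03)
#'
#' Per-tile histogram equalization of the 8-bit quantised in-FOV pixels
#' with clipped histograms (clip limit drawn uniformly, relative to the
#' uniform bin height) and bilinear interpolation of the tile mappings.
#' Delegates the equalization itself to `EBImage::clahe()`, padding by edge
#' replication so the frame divides into the tile grid. Outside-mask pixels
#' remain 0.
#'
#' @param image an [us_image()].
#' @param clip_range range to draw the clip limit from.
#' @param tiles tile grid size per axis (default 8, reduced for tiny
#'   frames).
#' @param draw optional previously drawn parameter list (`list(clip=)`).
#' @return the equalized `us_image`.
#' @export
clahe_enhance <- function(image, clip_range = c(1.0, 4.0), tiles = 8, draw = NULL) {
  if (is.null(draw)) draw <- list(clip = runif(1, clip_range[1], clip_range[2]))
  d <- dim(image$pixels)
  nt <- max(2, min(tiles, floor(min(d) / 4)))
  pr <- ceiling(d[1] / nt) * nt - d[1]
  pc <- ceiling(d[2] / nt) * nt - d[2]
  x <- quantize8(image$pixels)
  # fill the background with the in-FOV mean so tile histograms are not
  # dominated by out-of-FOV zeros (re-masked afterwards)
  if (any(image$mask > 0))
    x[image$mask == 0] <- quantize8(mean(x[image$mask > 0]))
  if (pr > 0) x <- rbind(x, x[rep(d[1], pr), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, rep(d[2], pc), drop = FALSE])
  y <- EBImage::clahe(x, nx = nt, ny = nt, bins = 256, limit = draw$clip)
  y <- matrix(as.numeric(y), nrow(x), ncol(x))[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  rewrap(image, y)
}

#' Gamma correction (B04)
#'
#' `output = input^gamma` on \[0, 1\], with gamma drawn log-uniformly.
#' Monotone for any positive gamma, so pixel ordering is preserved.
#'
#' @param image an [us_image()].
#' @param gamma_range range for the log-uniform gamma draw.
#' @param draw optional previously drawn parameter list (`list(gamma=)`).
#' @return the corrected `us_image`.
#' @export
gamma_correct <- function(image, gamma_range = c(0.7, 1.5), draw = NULL) {
  if (is.null(draw))
    draw <- list(gamma = exp(runif(1, log(gamma_range[1]), log(gamma_range[2]))))
  rewrap(image, image$pixels^draw$gamma)
}

#' Brightness and contrast change (B05)
#'
#' Linear remap `clip(a * input + b)` of the in-FOV pixels.
#'
#' @param image an [us_image()].
#' @param a_range range of the multiplicative term.
#' @param b_range range of the additive term.
#' @param draw optional previously drawn parameter list.
#' @return the remapped `us_image`.
#' @export
brightness_contrast <- function(image, a_range = c(0.8, 1.2),
                                b_range = c(-0.12, 0.12), draw = NULL) {
  if (is.null(draw)) draw <- list(a = runif(1, a_range[1], a_range[2]),
                                  b = runif(1, b_range[1], b_range[2]))
  inm <- image$mask > 0
  x <- image$pixels
  x[inm] <- draw$a * x[inm] + draw$b
  rewrap(image, x)
}

#' Depth change simulation (B06)
#'
#' Simulates changing the probe's depth setting: content is rescaled by a
#' drawn zoom factor, radially about the apex for fans and vertically about
#' the top edge of the FOV for linear geometries. The output mask and
#' geometry are identical to the input's (the FOV shape is preserved);
#' content sampled from beyond the original extent is 0.
#'
#' @param image an [us_image()] carrying geometry.
#' @param z_range zoom factor range (> 1 reveals deeper content, pulling a
#'   structure at depth `d` up to `d / z`).
#' @param draw optional previously drawn parameter list (`list(z=)`).
#' @return the rescaled `us_image`.
#' @export
depth_change <- function(image, z_range = c(0.85, 1.25), draw = NULL) {
  g <- image$geometry
  if (is.null(g)) stop("depth_change requires FOV geometry", call. = FALSE)
  if (is.null(draw)) draw <- list(z = runif(1, z_range[1], z_range[2]))
  if (draw$z == 1) return(image)
  shape <- dim(image$pixels)
  out <- matrix(0, shape[1], shape[2])
  idx <- which(image$mask > 0)
  row <- (idx - 1) %% shape[1]; col <- (idx - 1) %/% shape[1]
  if (g$kind == "linear") {
    srow <- g$r_min + (row - g$r_min) * draw$z
    scol <- col
  } else {
    dr <- row - g$apex[1]; dc <- col - g$apex[2]
    r <- sqrt(dr^2 + dc^2)
    th <- atan2(dc, dr)
    r2 <- g$r_min + (r - g$r_min) * draw$z
    srow <- g$apex[1] + r2 * cos(th)
    scol <- g$apex[2] + r2 * sin(th)
  }
  out[idx] <- bilinear_sample(image$pixels, srow, scol)
  rewrap(image, out)
}

#' Speckle noise simulation (B07)
#'
#' Multiplicative speckle: `clip(x + x * s)` where `s` is a zero-mean
#' Gaussian field smoothed with a small Gaussian kernel (sigma 1 px) to give
#' the granular spatial correlation characteristic of B-mode speckle.
#' Applied inside the FOV only.
#'
#' @param image an [us_image()].
#' @param params a [noise_params()] (uses `speckle_sigma`).
#' @param smooth_sigma smoothing kernel sigma in pixels.
#' @param draw optional previously drawn parameter list
#'   (`list(field_seed=)`).
#' @return the noised `us_image`.
#' @export
speckle_noise <- function(image, params = noise_params(), smooth_sigma = 1,
                          draw = NULL) {
  if (is.null(draw)) draw <- list(field_seed = draw_subseed())
  if (params$speckle_sigma == 0) return(image)
  d <- dim(image$pixels)
  s <- with_seed(draw$field_seed,
                 matrix(rnorm(prod(d), 0, params$speckle_sigma), d[1], d[2]))
  s <- gaussian_filter(s, smooth_sigma)
  rewrap(image, image$pixels + image$pixels * s)
}

#' Multiplicative Gaussian noise (B08)
#'
#' `clip(x * (1 + n))` with `n` i.i.d. normal per pixel, inside the FOV.
#'
#' @param image an [us_image()].
#' @param params a [noise_params()] (uses `gauss_sigma`).
#' @param draw optional previously drawn parameter list.
#' @return the noised `us_image`.
#' @export
gaussian_noise <- function(image, params = noise_params(), draw = NULL) {
  if (is.null(draw)) draw <- list(field_seed = draw_subseed())
  if (params$gauss_sigma == 0) return(image)
  d <- dim(image$pixels)
  n <- with_seed(draw$field_seed,
                 matrix(rnorm(prod(d), 0, params$gauss_sigma), d[1], d[2]))
  rewrap(image, image$pixels * (1 + n))
}

#' Salt-and-pepper noise (B09)
#'
#' Each in-FOV pixel is independently replaced, with probability
#' `sp_rate`, by 0 or 1 with equal probability.
#'
#' @param image an [us_image()].
#' @param params a [noise_params()] (uses `sp_rate`).
#' @param draw optional previously drawn parameter list.
#' @return the noised `us_image`.
#' @export
salt_pepper <- function(image, params = noise_params(), draw = NULL) {
  if (is.null(draw)) draw <- list(field_seed = draw_subseed())
  if (params$sp_rate == 0) return(image)
  inm <- which(image$mask > 0)
  x <- image$pixels
  vals <- with_seed(draw$field_seed, {
    hit <- runif(length(inm)) < params$sp_rate
    list(hit = hit, bw = (runif(length(inm)) < 0.5) * 1)
  })
  x[inm[vals$hit]] <- vals$bw[vals$hit]
  rewrap(image, x)
}

#' Rotation and shift (B11)
#'
#' Rotates about the image centre by a drawn angle and translates by drawn
#' per-axis fractions of the image dimensions; bilinear interpolation with
#' constant-0 fill. The mask is transformed identically and re-binarised,
#' and content is re-masked. The parametric geometry descriptor is dropped
#' (the warped FOV no longer matches a linear/fan model).
#'
#' @param image an [us_image()].
#' @param angle_range rotation range in degrees.
#' @param shift_frac maximum per-axis shift as a fraction of the dimension.
#' @param draw optional previously drawn parameter list
#'   (`list(angle=, dr=, dc=)`, angle in degrees, shifts in pixels).
#' @return the transformed `us_image`.
#' @export
rotate_shift <- function(image, angle_range = c(-15, 15), shift_frac = 0.1,
                         draw = NULL) {
  d <- dim(image$pixels)
  if (is.null(draw))
    draw <- list(angle = runif(1, angle_range[1], angle_range[2]),
                 dr = runif(1, -shift_frac, shift_frac) * d[1],
                 dc = runif(1, -shift_frac, shift_frac) * d[2])
  ctr <- (d - 1) / 2
  a <- draw$angle * pi / 180
  row <- rep(0:(d[1] - 1), times = d[2])
  col <- rep(0:(d[2] - 1), each = d[1])
  # inverse map: undo translation, then rotate backwards about the centre
  r1 <- row - draw$dr - ctr[1]
  c1 <- col - draw$dc - ctr[2]
  srow <- cos(a) * r1 + sin(a) * c1 + ctr[1]
  scol <- -sin(a) * r1 + cos(a) * c1 + ctr[2]
  px <- matrix(bilinear_sample(image$pixels, srow, scol), d[1], d[2])
  mk <- matrix(bilinear_sample(image$mask, srow, scol), d[1], d[2])
  rewrap(image, px, mask = (mk >= 0.5) * 1, geometry = NULL)
}
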