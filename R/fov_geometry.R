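#' Field-of-view geometry descriptor
#'
#' Parameterises the shape of an ultrasound field of view (FOV). Linear
#' probes image a rectangle; curvilinear and phased arrays image a circular
#' sector (fan) about a beam origin (the apex), which may lie above the image
#' frame. Angles are measured from the vertical centreline, positive
#' rightward; `theta0` is the angular half-width.
#'
#' @param kind one of `"linear"`, `"curvilinear"`, `"phased"`.
#' @param apex numeric `(row, col)` of the beam origin in 0-based pixel
#'   coordinates (row may be negative for fans).
#' @param theta0 angular half-width in radians; 0 for linear, in
#'   (0, pi/2) otherwise.
#' @param r_min,r_max radial range in pixels from the apex. For linear
#'   geometries these are the top and bottom image rows of the rectangle.
#'   Phased arrays have `r_min <= 0.05 * r_max`.
#' @param width lateral extent in pixels (linear only).
#' @return an object of class `fov_geometry`.
#' @export
#' @examples
#' g <- fov_geometry("curvilinear", apex = c(-30, 63.5), theta0 = 0.5,
#'                   r_min = 60, r_max = 150)
#' bottom_corners(g)
fov_geometry <- function(kind = c("linear", "curvilinear", "phased"),
                         apex, theta0 = 0, r_min, r_max, width = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    if (theta0 != 0) stop("linear geometry requires theta0 = 0", call. = FALSE)
    if (is.null(width)) stop("linear geometry requires `width`", call. = FALSE)
  } else {
    if (theta0 <= 0 || theta0 >= pi / 2)
      stop("fan geometry requires 0 < theta0 < pi/2", call. = FALSE)
  }
  if (r_min >= r_max) stop("r_min must be < r_max", call. = FALSE)
  if (kind == "phased" && r_min > 0.05 * r_max)
    stop("phased geometry requires r_min <= 0.05 * r_max", call. = FALSE)
  structure(
    list(kind = kind, apex = as.numeric(apex), theta0 = theta0,
         r_min = r_min, r_max = r_max, width = width),
    class = "fov_geometry")
}

#' @export
print.fov_geometry <- function(x, ...) {
  cat(sprintf("<fov_geometry %s, apex (%.1f, %.1f), theta0 %.3f, r [%.1f, %.1f]%s>\n",
              x$kind, x$apex[1], x$apex[2], x$theta0, x$r_min, x$r_max,
              if (!is.null(x$width)) sprintf(", width %.1f", x$width) else ""))
  invisible(x)
}

#' Bottom corner points of a field of view
#'
#' The two `(row, col)` points where the outer arc meets the lateral FOV
#' edges. Their lateral separation is `2 * r_max * sin(theta0)` for fans,
#' strictly increasing in `theta0` at fixed `r_max`.
#'
#' @param geometry an [fov_geometry()].
#' @return a 2x2 matrix; rows are the left and right corner `(row, col)`.
#' @export
bottom_corners <- function(geometry) {
  g <- geometry
  if (g$kind == "linear") {
    rbind(c(g$r_max, g$apex[2] - g$width / 2),
          c(g$r_max, g$apex[2] + g$width / 2))
  } else {
    rbind(c(g$apex[1] + g$r_max * cos(g$theta0), g$apex[2] - g$r_max * sin(g$theta0)),
          c(g$apex[1] + g$r_max * cos(g$theta0), g$apex[2] + g$r_max * sin(g$theta0)))
  }
}

#' Render a binary FOV mask from a geometry
#'
#' A pixel is inside the mask iff its centre lies within the angular sector
#' `[-theta0, theta0]` and radial band `[r_min, r_max]` about the apex
#' (linear: within the rectangle).
#'
#' @param geometry an [fov_geometry()].
#' @param shape integer `(rows, cols)` of the target frame.
#' @return a binary matrix of dimension `shape`.
#' @export
render_fov_mask <- function(geometry, shape) {
  g <- geometry
  nr <- shape[1]; nc <- shape[2]
  row <- matrix(rep(0:(nr - 1), nc), nr, nc)
  col <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  if (g$kind == "linear") {
    m <- (row >= g$r_min & row <= g$r_max &
          abs(col - g$apex[2]) <= g$width / 2) * 1
  } else {
    dr <- row - g$apex[1]; dc <- col - g$apex[2]
    r <- sqrt(dr^2 + dc^2)
    th <- atan2(dc, dr)
    m <- (dr > 0 & r >= g$r_min & r <= g$r_max & abs(th) <= g$theta0) * 1
  }
  if (sum(m) == 0) stop("geometry lies entirely outside the frame", call. = FALSE)
  m
}

#' Apply the binary FOV mask to an image
#'
#' Element-wise multiplication of the pixel grid with the binary mask, so
#' every pixel outside the field of view is exactly 0. Mask and geometry are
#' unchanged.
#'
#' @param image an [us_image()].
#' @return the masked `us_image`.
#' @export
apply_mask <- function(image) {
  stopifnot(inherits(image, "us_image"))
  if (!all(dim(image$mask) == dim(image$pixels)))
    stop("mask and pixels have different shapes", call. = FALSE)
  image$pixels <- image$pixels * image$mask
  image
}

#' Crop an image to the tight bounding box of its FOV mask
#'
#' Output dimensions equal the smallest rectangle containing all nonzero
#' mask pixels (inclusive). Geometry coordinates are shifted accordingly.
#' Idempotent.
#'
#' @param image an [us_image()] (mask must be non-empty).
#' @return the cropped `us_image`.
#' @export
crop_to_fov <- function(image) {
  stopifnot(inherits(image, "us_image"))
  nz <- which(image$mask > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("cannot crop: FOV mask is empty", call. = FALSE)
  r1 <- min(nz[, 1]); r2 <- max(nz[, 1])
  c1 <- min(nz[, 2]); c2 <- max(nz[, 2])
  image$pixels <- image$pixels[r1:r2, c1:c2, drop = FALSE]
  image$mask <- image$mask[r1:r2, c1:c2, drop = FALSE]
  if (!is.null(image$geometry)) {
    g <- image$geometry
    g$apex <- g$apex - c(r1 - 1, c1 - 1)
    if (g$kind == "linear") {
      g$r_min <- g$r_min - (r1 - 1)
      g$r_max <- g$r_max - (r1 - 1)
    }
    image$geometry <- g
  }
  image
}

#' Estimate a binary FOV mask from pixel intensities
#'
#' Stand-in mask estimator for clean or synthetic inputs: thresholds the
#' image at a small fixed intensity, applies a 5x5 morphological closing,
#' keeps the largest connected component and fills its holes. Real scanner
#' frames with vendor overlays should use externally supplied masks instead.
#'
#' @param pixels numeric matrix in \[0, 1\] (or 0-255, rescaled).
#' @param threshold intensity threshold (default 2/255).
#' @return a binary matrix.
#' @export
estimate_fov_mask <- function(pixels, threshold = 2 / 255) {
  if (max(pixels) > 1) pixels <- pixels / 255
  bw <- (pixels >= threshold) * 1
  if (sum(bw) == 0) stop("no pixel above threshold; cannot estimate FOV mask",
                         call. = FALSE)
  closed <- EBImage::closing(bw, EBImage::makeBrush(5, shape = "box"))
  lab <- EBImage::bwlabel(closed)
  if (max(lab) == 0) stop("no connected component found", call. = FALSE)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  comp <- (lab == keep) * 1
  filled <- EBImage::fillHull(comp)
  m <- matrix(as.numeric(filled > 0.5), nrow(pixels), ncol(pixels))
  m
}

# subpixel boundary samples of a mask: per-row lateral edges and per-column
# vertical edges, each pushed half a pixel outward; samples on the frame
# border are excluded (there the mask is clipped, not a model boundary)
sector_boundary_samples <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nr)) {
    cc <- which(mask[r, ] > 0)
    if (length(cc) == 0) next
    if (min(cc) > 1) pts <- rbind(pts, c(r - 1, min(cc) - 1.5))
    if (max(cc) < nc) pts <- rbind(pts, c(r - 1, max(cc) - 0.5))
  }
  for (cl in seq_len(nc)) {
    rw <- which(mask[, cl] > 0)
    if (length(rw) == 0) next
    if (min(rw) > 1) pts <- rbind(pts, c(min(rw) - 1.5, cl - 1))
    if (max(rw) < nr) pts <- rbind(pts, c(max(rw) - 0.5, cl - 1))
  }
  pts
}

# total-least-squares line through (row, col) points: returns centre point
# and unit direction (via principal axis)
tls_line <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  dir <- sv$v[, 1]
  if (dir[1] < 0) dir <- -dir   # orient downward (increasing row)
  resid <- abs(x[, 1] * dir[2] - x[, 2] * dir[1])  # perpendicular distances
  list(centre = ctr, dir = dir, rms = sqrt(mean(resid^2)))
}

# intersection of two lines given as centre + direction
line_intersect <- function(l1, l2) {
  # solve c1 + t1 d1 = c2 + t2 d2
  A <- cbind(l1$dir, -l2$dir)
  b <- l2$centre - l1$centre
  if (abs(det(A)) < 1e-9) return(NULL)
  t <- solve(A, b)
  l1$centre + t[1] * l1$dir
}

#' Fit an FOV geometry to a binary mask
#'
#' Classifies linear versus fan by testing whether nonzero row-widths are
#' constant with depth, then (for fans) estimates the apex by
#' total-least-squares fits to the two lateral flank edges, and `theta0`,
#' `r_min`, `r_max` from the mask extremes. Phased iff
#' `r_min / r_max < 0.05`.
#'
#' @param mask binary matrix with at least one nonzero pixel.
#' @param edge_tol permissible RMS residual (pixels) of the flank-line fits.
#' @return an [fov_geometry()].
#' @export
fit_fov_geometry <- function(mask, edge_tol = 1.5) {
  nzr <- which(rowSums(mask) > 0)
  if (length(nzr) == 0) stop("mask is empty", call. = FALSE)
  left <- right <- rep(NA_real_, length(nzr))
  for (i in seq_along(nzr)) {
    cc <- which(mask[nzr[i], ] > 0)
    # subpixel: the true boundary lies half a pixel outside the outermost
    # covered pixel centre
    left[i] <- min(cc) - 1 - 0.5
    right[i] <- max(cc) - 1 + 0.5
  }
  width <- right - left + 1
  rows0 <- nzr - 1
  if (max(width) - min(width) <= max(2, 0.02 * max(width)) &&
      max(left) - min(left) <= max(2, 0.02 * max(width))) {
    w <- stats::median(width)
    return(fov_geometry("linear",
                        apex = c(min(rows0), stats::median((left + right) / 2)),
                        theta0 = 0, r_min = min(rows0), r_max = max(rows0),
                        width = w - 1))
  }
  # fan: fit flank lines on a mid-depth band, then refine once
  fit_once <- function(sel) {
    if (sum(sel) < 5) return(NULL)
    lf <- tls_line(cbind(rows0[sel], left[sel]))
    rf <- tls_line(cbind(rows0[sel], right[sel]))
    apex <- line_intersect(lf, rf)
    if (is.null(apex)) return(NULL)
    ang_l <- atan2(lf$dir[2], lf$dir[1])
    ang_r <- atan2(rf$dir[2], rf$dir[1])
    list(apex = apex, theta0 = (ang_r - ang_l) / 2,
         rms = max(lf$rms, rf$rms))
  }
  n <- length(rows0)
  band <- seq_along(rows0) >= stats::quantile(seq_len(n), 0.3) &
          seq_along(rows0) <= stats::quantile(seq_len(n), 0.6)
  est <- fit_once(band)
  if (is.null(est)) stop("FOV mask fits neither linear nor fan model", call. = FALSE)
  # radial extremes from all mask pixels
  radial_range <- function(apex) {
    nz <- which(mask > 0, arr.ind = TRUE)
    r <- sqrt((nz[, 1] - 1 - apex[1])^2 + (nz[, 2] - 1 - apex[2])^2)
    # the arcs pass half a pixel beyond the extreme covered centres
    c(min(r) - 0.5, max(r) + 0.5)
  }
  rr <- radial_range(est$apex)
  # refine: keep only rows where both flanks are straight (between the inner
  # arc bottom and the outer corner row)
  lo <- est$apex[1] + rr[1] + 2
  hi <- est$apex[1] + rr[2] * cos(est$theta0) - 2
  band2 <- rows0 > lo & rows0 < hi
  est2 <- fit_once(band2)
  if (!is.null(est2) && est2$rms <= est$rms) est <- est2
  rr <- radial_range(est$apex)
  # refine all five parameters jointly by least squares on subpixel
  # boundary samples (extrapolated flank lines alone pin the apex poorly)
  bp <- sector_boundary_samples(mask)
  if (nrow(bp) >= 20) {
    obj <- function(par) {
      dr <- bp[, 1] - par[1]; dc <- bp[, 2] - par[2]
      r <- sqrt(dr^2 + dc^2)
      th <- atan2(dc, dr)
      d <- pmin(abs(r - par[5]), abs(r - par[4]),
                r * abs(abs(th) - par[3]))
      mean(d^2)
    }
    op <- stats::optim(c(est$apex, est$theta0, rr[1], rr[2]), obj,
                       control = list(maxit = 600, reltol = 1e-10))
    if (op$par[3] > 0.01 && op$par[3] < pi / 2 &&
        op$par[4] >= 0 && op$par[4] < op$par[5] &&
        sqrt(op$value) < edge_tol) {
      est$apex <- op$par[1:2]
      est$theta0 <- op$par[3]
      est$rms <- min(est$rms, sqrt(op$value))
      # r_min is unconstrained when the inner arc is clipped at the frame
      # border; take it from the radial extremes under the refined apex
      rr <- c(radial_range(est$apex)[1], op$par[5])
    }
  }
  if (est$rms > edge_tol)
    stop("FOV mask fits neither linear nor fan model (edge residual ",
         sprintf("%.2f", est$rms), " px)", call. = FALSE)
  if (est$theta0 <= 0 || est$theta0 >= pi / 2)
    stop("implausible fitted angular half-width", call. = FALSE)
  kind <- if (rr[1] / rr[2] < 0.05) "phased" else "curvilinear"
  r_min <- if (kind == "phased") min(rr[1], 0.05 * rr[2]) else rr[1]
  fov_geometry(kind, apex = est$apex, theta0 = est$theta0,
               r_min = r_min, r_max = rr[2])
}

#' Scan-convert a beam-space image to Cartesian display coordinates
#'
#' Beam space has rows indexing depth (radius) and columns indexing beam
#' angle (fans) or lateral position (linear). Each Cartesian pixel inside
#' the rendered FOV mask is bilinearly interpolated from beam space; pixels
#' outside are 0. For linear geometries scan conversion is the identity on
#' the in-FOV rectangle.
#'
#' @param beam_image numeric matrix in beam space.
#' @param geometry target [fov_geometry()].
#' @param shape output `(rows, cols)`; default just encloses the FOV.
#' @return an [us_image()] carrying the rendered mask and `geometry`.
#' @export
scan_convert <- function(beam_image, geometry, shape = NULL) {
  g <- geometry
  if (is.null(shape)) {
    bc <- bottom_corners(g)
    shape <- c(ceiling(max(bc[, 1])) + 1,
               ceiling(max(bc[, 2])) + 1)
  }
  mask <- render_fov_mask(g, shape)
  out <- matrix(0, shape[1], shape[2])
  idx <- which(mask > 0)
  row <- (idx - 1) %% shape[1]
  col <- (idx - 1) %/% shape[1]
  nbr <- nrow(beam_image); nbc <- ncol(beam_image)
  if (g$kind == "linear") {
    br <- (row - g$r_min) / max(g$r_max - g$r_min, 1e-9) * (nbr - 1)
    bc <- (col - (g$apex[2] - g$width / 2)) / max(g$width, 1e-9) * (nbc - 1)
  } else {
    dr <- row - g$apex[1]; dc <- col - g$apex[2]
    r <- sqrt(dr^2 + dc^2)
    th <- atan2(dc, dr)
    br <- (r - g$r_min) / (g$r_max - g$r_min) * (nbr - 1)
    bc <- (th + g$theta0) / (2 * g$theta0) * (nbc - 1)
  }
  out[idx] <- bilinear_sample(beam_image, br, bc)
  us_image(out, mask, geometry = g)
}

#' Resample a fan-shaped image back onto a regular beam-space lattice
#'
#' Inverse of [scan_convert()]: samples the Cartesian image on a regular
#' (radius, angle) lattice at the same depth resolution
#' (`round(r_max - r_min)` rows). Linear input is returned as the in-FOV
#' rectangle unchanged (a no-op, with a message).
#'
#' @param image an [us_image()] with geometry.
#' @return a numeric matrix in beam space.
#' @export
inverse_scan_convert <- function(image) {
  g <- image$geometry
  if (is.null(g)) stop("image has no FOV geometry", call. = FALSE)
  if (g$kind == "linear") {
    if (getOption("lusaug.verbose", FALSE))
      message("linear geometry: inverse scan conversion is a no-op")
    c1 <- round(g$apex[2] - g$width / 2) + 1
    c2 <- round(g$apex[2] + g$width / 2) + 1
    r1 <- round(g$r_min) + 1; r2 <- round(g$r_max) + 1
    nr <- nrow(image$pixels); nc <- ncol(image$pixels)
    return(image$pixels[max(r1, 1):min(r2, nr), max(c1, 1):min(c2, nc), drop = FALSE])
  }
  n_r <- max(2, round(g$r_max - g$r_min))
  n_c <- max(2, round(2 * g$r_max * sin(g$theta0)))
  r <- g$r_min + (seq_len(n_r) - 1) / (n_r - 1) * (g$r_max - g$r_min)
  th <- -g$theta0 + (seq_len(n_c) - 1) / (n_c - 1) * (2 * g$theta0)
  rr <- rep(r, times = n_c); tt <- rep(th, each = n_r)
  srow <- g$apex[1] + rr * cos(tt)
  scol <- g$apex[2] + rr * sin(tt)
  matrix(bilinear_sample(image$pixels, srow, scol), n_r, n_c)
}
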