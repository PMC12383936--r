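# Synthetic B-mode lung ultrasound phantoms. These are schematic, not
# physically simulated: their purpose is to place the canonical lung
# ultrasound findings (pleural line, A-line reverberations, B-line rays,
# anechoic effusion) at known locations inside a known FOV, so geometric and
# intensity invariants have ground truth and the ablation harness has a
# learnable dataset without any external download.

#' Specification of one synthetic lung ultrasound phantom
#'
#' @param geometry an [fov_geometry()] describing the FOV to render into.
#' @param pleural_depth fraction of the radial range at which the bright
#'   pleural line sits (in (0.1, 0.6)).
#' @param n_alines number of A-line reverberation replicas (equally spaced
#'   dimming copies of the pleural line at integer multiples of the
#'   probe-pleura distance).
#' @param n_blines number of bright B-line rays running from the pleural
#'   line to the outer arc.
#' @param effusion logical; add an anechoic (dark) fluid wedge at the
#'   pleural line.
#' @param speckle_texture_sigma spatial correlation (pixels) of the
#'   background speckle texture.
#' @param label ground-truth class, one of `"A"`, `"B"`, `"effusion"`,
#'   `"normal"`; must be consistent with the counts (A implies no B-lines,
#'   B implies at least one).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry, pleural_depth = 0.35, n_alines = 2,
                         n_blines = 0, effusion = FALSE,
                         speckle_texture_sigma = 1,
                         label = c("A", "B", "effusion", "normal")) {
  label <- match.arg(label)
  if (pleural_depth <= 0.1 || pleural_depth >= 0.6)
    stop("pleural_depth must lie in (0.1, 0.6)", call. = FALSE)
  if (n_alines < 0 || n_blines < 0) stop("artifact counts must be >= 0", call. = FALSE)
  if (label == "A" && n_blines != 0)
    stop("label 'A' requires n_blines = 0", call. = FALSE)
  if (label == "B" && n_blines < 1)
    stop("label 'B' requires n_blines >= 1", call. = FALSE)
  structure(list(geometry = geometry, pleural_depth = pleural_depth,
                 n_alines = n_alines, n_blines = n_blines,
                 effusion = effusion,
                 speckle_texture_sigma = speckle_texture_sigma, label = label),
            class = "phantom_spec")
}

#' Render a synthetic lung ultrasound phantom
#'
#' Renders in beam space (depth x beam angle) and scan-converts through the
#' spec's geometry: a multiplicative speckle background with log
#' compression, a bright pleural band, dimming A-line replicas at integer
#' multiples of the probe-pleura distance, full-depth B-line rays at random
#' angles, and an optional anechoic effusion wedge. Uses the current RNG
#' state; seed with [with_seed()] or `set.seed()` for reproducibility.
#'
#' @param spec a [phantom_spec()].
#' @param shape output `(rows, cols)` (default 128x128).
#' @param patient_id,video_id bookkeeping labels attached to the output.
#' @return an [us_image()] with ground-truth mask, geometry and label.
#' @export
#' @examples
#' g <- fov_geometry("curvilinear", apex = c(-20, 63.5), theta0 = 0.5,
#'                   r_min = 40, r_max = 145)
#' ph <- with_seed(1, generate_phantom(phantom_spec(g, label = "A")))
generate_phantom <- function(spec, shape = c(128, 128),
                             patient_id = NA_character_, video_id = NA_character_) {
  g <- spec$geometry
  if (g$kind == "linear") {
    n_r <- max(8, round(g$r_max - g$r_min))
    n_c <- max(8, round(g$width))
  } else {
    n_r <- max(8, round(g$r_max - g$r_min))
    n_c <- max(8, round(2 * g$r_max * sin(g$theta0)))
  }
  t_depth <- (seq_len(n_r) - 1) / (n_r - 1)        # 0..1 depth fraction

  # multiplicative speckle over a gently attenuating base, log-compressed
  base <- 0.55 * exp(-0.6 * t_depth)
  tex <- matrix(stats::rexp(n_r * n_c), n_r, n_c)
  tex <- gaussian_filter(tex, spec$speckle_texture_sigma)
  beam <- base * tex
  beam <- log(1 + 20 * beam) / log(1 + 21)

  depth_band <- function(centre_frac, amp, width_px = 2) {
    prof <- amp * exp(-((seq_len(n_r) - 1) - centre_frac * (n_r - 1))^2 /
                        (2 * width_px^2))
    matrix(rep(prof, n_c), n_r, n_c)
  }

  if (spec$effusion) {
    # anechoic wedge just below the pleural line over a random angular span
    c0 <- floor(runif(1, 0, n_c * 0.5))
    cw <- floor(runif(1, n_c * 0.4, n_c * 0.5))
    rows <- which(t_depth >= spec$pleural_depth &
                    t_depth <= spec$pleural_depth + 0.25)
    cols <- (c0 + seq_len(cw)) %% n_c + 1
    beam[rows, cols] <- beam[rows, cols] * 0.08
  }

  beam <- beam + depth_band(spec$pleural_depth, 0.85)      # pleural line
  if (spec$n_alines > 0) {
    for (i in seq_len(spec$n_alines)) {
      d <- spec$pleural_depth * (i + 1)
      if (d <= 1) beam <- beam + depth_band(d, 0.85 * 0.5^i)
    }
  }
  if (spec$n_blines > 0) {
    # a B-line is a bright ray at fixed beam angle from the pleura downward
    start_row <- max(1, round(spec$pleural_depth * (n_r - 1)))
    for (i in seq_len(spec$n_blines)) {
      cc <- floor(runif(1, 1, n_c - 1))
      cols <- intersect(cc + (-1:1), seq_len(n_c))
      beam[start_row:n_r, cols] <-
        pmax(beam[start_row:n_r, cols], 0.8)
    }
  }
  beam <- clip01(beam)

  out <- scan_convert(beam, g, shape = shape)
  out$patient_id <- patient_id
  out$label <- spec$label
  attr(out, "video_id") <- video_id
  out
}

random_geometry <- function(shape) {
  h <- shape[1]; w <- shape[2]
  kind <- sample(c("linear", "curvilinear", "phased"), 1)
  if (kind == "linear") {
    fov_geometry("linear", apex = c(0, (w - 1) / 2), theta0 = 0,
                 r_min = 0, r_max = h - 1, width = w - 1)
  } else {
    theta0 <- runif(1, 0.35, 0.65)
    rho <- if (kind == "phased") 0.02 else runif(1, 0.12, 0.25)
    r_max <- min((h - 1) / (1 - rho), ((w - 1) / 2) / sin(theta0))
    fov_geometry(kind, apex = c(-rho * r_max, (w - 1) / 2), theta0 = theta0,
                 r_min = rho * r_max, r_max = r_max)
  }
}

random_phantom_spec <- function(label, geometry) {
  switch(label,
         A = phantom_spec(geometry, pleural_depth = runif(1, 0.25, 0.45),
                          n_alines = sample(1:3, 1), n_blines = 0, label = "A"),
         B = phantom_spec(geometry, pleural_depth = runif(1, 0.25, 0.45),
                          n_alines = sample(0:1, 1), n_blines = sample(1:3, 1),
                          label = "B"),
         effusion = phantom_spec(geometry, pleural_depth = runif(1, 0.25, 0.45),
                                 n_alines = sample(0:1, 1), n_blines = 0,
                                 effusion = TRUE, label = "effusion"),
         normal = phantom_spec(geometry, pleural_depth = runif(1, 0.25, 0.45),
                               n_alines = 0, n_blines = 0, label = "normal"))
}

#' Generate a synthetic phantom dataset with patient structure
#'
#' Mirrors the patient / video / frame hierarchy of clinical lung
#' ultrasound collections: each patient gets one FOV geometry; labels are
#' drawn per video and apply to every frame of that video; frames within a
#' video share the phantom layout and differ in speckle realisation.
#' Deterministic given `seed`.
#'
#' @param n_patients number of patients (>= 1).
#' @param videos_per_patient,frames_per_video hierarchy counts.
#' @param class_mix named probabilities over
#'   `c("A", "B", "effusion", "normal")`; must sum to 1.
#' @param shape image `(rows, cols)`.
#' @param seed master integer seed.
#' @return a list of class `phantom_dataset` with `images` (list of
#'   [us_image()]) and `manifest` (a tibble: image, patient_id, video_id,
#'   frame, label, fov_kind).
#' @export
generate_dataset <- function(n_patients, videos_per_patient = 1,
                             frames_per_video = 1,
                             class_mix = c(A = 0.25, B = 0.25,
                                           effusion = 0.25, normal = 0.25),
                             shape = c(128, 128), seed = 1) {
  stopifnot(n_patients >= 1, videos_per_patient >= 1, frames_per_video >= 1)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1", call. = FALSE)
  images <- list()
  rows <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    geom <- with_seed(substream_seed(seed, pid, "geom"), random_geometry(shape))
    for (v in seq_len(videos_per_patient)) {
      vid <- sprintf("%s-V%02d", pid, v)
      lab <- with_seed(substream_seed(seed, vid, "label"),
                       sample(names(class_mix), 1, prob = class_mix))
      sp <- with_seed(substream_seed(seed, vid, "spec"),
                      random_phantom_spec(lab, geom))
      for (f in seq_len(frames_per_video)) {
        img <- with_seed(substream_seed(seed, vid, f, "render"),
                         generate_phantom(sp, shape = shape,
                                          patient_id = pid, video_id = vid))
        images[[length(images) + 1]] <- img
        rows[[length(rows) + 1]] <-
          tibble::tibble(image = length(images), patient_id = pid,
                         video_id = vid, frame = f, label = lab,
                         fov_kind = geom$kind)
      }
    }
  }
  structure(list(images = images, manifest = do.call(rbind, rows)),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset: %d images, %d patients>\n",
              length(x$images), length(unique(x$manifest$patient_id))))
  print(table(x$manifest$label))
  invisible(x)
}

#' Write a phantom dataset to disk (PNGs, masks, CSV manifest)
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if absent).
#' @return the manifest tibble (with `path` and `mask_path` columns),
#'   invisibly; also written as `manifest.csv`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$path <- sprintf("%s/img_%04d.png", dir, man$image)
  man$mask_path <- sprintf("%s/mask_%04d.png", dir, man$image)
  for (i in seq_len(nrow(man)))
    write_us_image(dataset$images[[man$image[i]]], man$path[i], man$mask_path[i])
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
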