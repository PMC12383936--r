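# Transform registry and pipeline composition. A pipeline is an ordered
# sequence of transform specs, each applied with an independent Bernoulli
# probability; randomness is organised into per-(image, view, transform)
# substreams so that removing one transform never shifts the draws of the
# others (important for low-noise leave-one-out comparisons).

.registry <- new.env(parent = emptyenv())

reg_add <- function(id, label, cfg, draw, apply) {
  assign(id, list(id = id, label = label, cfg = cfg, draw = draw, apply = apply),
         envir = .registry)
}

reg_get <- function(id) {
  if (!exists(id, envir = .registry))
    stop("unknown transform id: ", id, call. = FALSE)
  get(id, envir = .registry)
}

#' Registered transform identifiers
#'
#' @return character vector of the registered ids ("A00".."A05",
#'   "B00".."B11").
#' @export
transform_ids <- function() sort(ls(envir = .registry))

no_draw <- function(image, cfg) list()

register_builtin_transforms <- function() {
  reg_add("A00", "Crop and resize",
          list(c_min = 0.08, c_max = 1.0, aspect_range = c(3 / 4, 4 / 3),
               out_size = c(128, 128)),
          function(image, cfg) draw_crop(image, cfg),
          function(image, params, cfg) apply_crop(image, params, cfg))
  reg_add("A01", "Horizontal reflection", list(), no_draw,
          function(image, params, cfg) horizontal_reflect(image))
  reg_add("A02", "Colour jitter",
          list(brightness = 0.8, contrast = 0.8, saturation = 0.8, hue = 0.2),
          function(image, cfg) draw_jitter(image, cfg),
          function(image, params, cfg) apply_jitter(image, params, cfg))
  reg_add("A03", "Conversion to grayscale", list(), no_draw,
          function(image, params, cfg) to_grayscale(image))
  reg_add("A04", "Gaussian blur", list(sigma_range = c(0.1, 2.0)),
          function(image, cfg) list(sigma = runif(1, cfg$sigma_range[1], cfg$sigma_range[2])),
          function(image, params, cfg) gaussian_blur(image, draw = params))
  reg_add("A05", "Solarization", list(threshold = 0.5), no_draw,
          function(image, params, cfg) solarize(image, threshold = cfg$threshold))
  reg_add("B00", "Probe type change",
          list(theta0_range = c(0.3, 0.7), r_min_frac = 0.15),
          function(image, cfg) list(theta0 = runif(1, cfg$theta0_range[1], cfg$theta0_range[2])),
          function(image, params, cfg)
            probe_type_change(image, r_min_frac = cfg$r_min_frac, draw = params))
  reg_add("B01", "Convexity change",
          list(m_range = c(0.7, 1.3), theta0_bounds = c(0.1, 1.2)),
          function(image, cfg) list(m = runif(1, cfg$m_range[1], cfg$m_range[2])),
          function(image, params, cfg)
            convexity_change(image, theta0_bounds = cfg$theta0_bounds, draw = params))
  reg_add("B02", "Wavelet denoising", list(levels = 3, alpha = 3, m = NULL),
          no_draw,
          function(image, params, cfg)
            wavelet_denoise(image, levels = cfg$levels, alpha = cfg$alpha, m = cfg$m))
  reg_add("B03", "CLAHE", list(clip_range = c(1.0, 4.0), tiles = 8),
          function(image, cfg) list(clip = runif(1, cfg$clip_range[1], cfg$clip_range[2])),
          function(image, params, cfg)
            clahe_enhance(image, tiles = cfg$tiles, draw = params))
  reg_add("B04", "Gamma correction", list(gamma_range = c(0.7, 1.5)),
          function(image, cfg)
            list(gamma = exp(runif(1, log(cfg$gamma_range[1]), log(cfg$gamma_range[2])))),
          function(image, params, cfg) gamma_correct(image, draw = params))
  reg_add("B05", "Brightness and contrast change",
          list(a_range = c(0.8, 1.2), b_range = c(-0.12, 0.12)),
          function(image, cfg) list(a = runif(1, cfg$a_range[1], cfg$a_range[2]),
                                    b = runif(1, cfg$b_range[1], cfg$b_range[2])),
          function(image, params, cfg) brightness_contrast(image, draw = params))
  reg_add("B06", "Depth change simulation", list(z_range = c(0.85, 1.25)),
          function(image, cfg) list(z = runif(1, cfg$z_range[1], cfg$z_range[2])),
          function(image, params, cfg) depth_change(image, draw = params))
  reg_add("B07", "Speckle noise simulation",
          list(speckle_sigma = 0.25, smooth_sigma = 1),
          function(image, cfg) list(field_seed = draw_subseed()),
          function(image, params, cfg)
            speckle_noise(image, params = noise_params(speckle_sigma = cfg$speckle_sigma),
                          smooth_sigma = cfg$smooth_sigma, draw = params))
  reg_add("B08", "Gaussian noise", list(gauss_sigma = 0.1),
          function(image, cfg) list(field_seed = draw_subseed()),
          function(image, params, cfg)
            gaussian_noise(image, params = noise_params(gauss_sigma = cfg$gauss_sigma),
                           draw = params))
  reg_add("B09", "Salt and pepper noise", list(sp_rate = 0.01),
          function(image, cfg) list(field_seed = draw_subseed()),
          function(image, params, cfg)
            salt_pepper(image, params = noise_params(sp_rate = cfg$sp_rate),
                        draw = params))
  reg_add("B10", "Horizontal reflection", list(), no_draw,
          function(image, params, cfg) horizontal_reflect(image))
  reg_add("B11", "Rotation and shift",
          list(angle_range = c(-15, 15), shift_frac = 0.1),
          function(image, cfg) {
            d <- dim(image$pixels)
            list(angle = runif(1, cfg$angle_range[1], cfg$angle_range[2]),
                 dr = runif(1, -cfg$shift_frac, cfg$shift_frac) * d[1],
                 dc = runif(1, -cfg$shift_frac, cfg$shift_frac) * d[2])
          },
          function(image, params, cfg) rotate_shift(image, draw = params))
}

.onLoad <- function(libname, pkgname) register_builtin_transforms()

#' One stochastic transformation in a pipeline
#'
#' @param id registered transform identifier ("A00".."A05", "B00".."B11").
#' @param probability application probability in \[0, 1\].
#' @param params named list of parameter overrides for the transform's
#'   configuration.
#' @return a list of class `transform_spec`.
#' @export
transform_spec <- function(id, probability, params = list()) {
  reg_get(id)
  stopifnot(probability >= 0, probability <= 1)
  structure(list(id = id, probability = probability, params = params),
            class = "transform_spec")
}

#' An ordered augmentation pipeline
#'
#' @param name pipeline name.
#' @param specs list of [transform_spec()]s; ids must be unique and order is
#'   preserved.
#' @param out_size final output `(rows, cols)` after the closing resize.
#' @return a list of class `augmentation_pipeline`.
#' @export
augmentation_pipeline <- function(name, specs, out_size = c(128, 128)) {
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate transform ids in pipeline", call. = FALSE)
  structure(list(name = name, specs = specs, out_size = out_size),
            class = "augmentation_pipeline")
}

#' @export
print.augmentation_pipeline <- function(x, ...) {
  cat(sprintf("<augmentation_pipeline '%s', %d transforms, out %dx%d>\n",
              x$name, length(x$specs), x$out_size[1], x$out_size[2]))
  for (s in x$specs)
    cat(sprintf("  %s  p=%.3f  %s\n", s$id, s$probability, reg_get(s$id)$label))
  invisible(x)
}

#' Pipeline identifiers in order
#'
#' @param pipeline an [augmentation_pipeline()].
#' @return character vector of transform ids.
#' @export
pipeline_ids <- function(pipeline)
  vapply(pipeline$specs, `[[`, character(1), "id")

# application probabilities by id, as printed in the pipeline tables
.table_prob <- c(A00 = 1.0, A01 = 0.5, A02 = 0.8, A03 = 0.2, A04 = 0.5, A05 = 0.1,
                 B00 = 0.3, B01 = 0.75, B02 = 0.5, B03 = 0.2, B04 = 0.5, B05 = 0.5,
                 B06 = 0.5, B07 = 0.333, B08 = 0.333, B09 = 0.1, B10 = 0.5, B11 = 0.5)

#' Construct one of the three built-in pipelines
#'
#' `"standard_aug"` is the photographic baseline (A00-A05);
#' `"aug_us_o"` is the twelve-transform ultrasound-specific pipeline
#' (B00-B11); `"aug_us_d"` is the distilled pipeline
#' `[B03, A02, B11, A00]`, keeping each transform's application
#' probability from its source pipeline.
#'
#' @param name one of `"standard_aug"`, `"aug_us_o"`, `"aug_us_d"`.
#' @param out_size final output size (default 128x128).
#' @return an [augmentation_pipeline()].
#' @export
#' @examples
#' pipeline_ids(builtin_pipeline("aug_us_d"))
builtin_pipeline <- function(name = c("standard_aug", "aug_us_o", "aug_us_d"),
                             out_size = c(128, 128)) {
  name <- match.arg(name)
  ids <- switch(name,
                standard_aug = paste0("A0", 0:5),
                aug_us_o = sprintf("B%02d", 0:11),
                aug_us_d = c("B03", "A02", "B11", "A00"))
  specs <- lapply(ids, function(id) transform_spec(id, unname(.table_prob[id])))
  augmentation_pipeline(name, specs, out_size = out_size)
}

#' Apply an augmentation pipeline to an image
#'
#' Iterates the specs in order; for each, draws an independent Bernoulli
#' gate with the spec's probability and, on success, applies the transform
#' with freshly drawn parameters. The gate is drawn before the parameter
#' draw and every (image, view, transform) combination has its own random
#' substream derived from the master seed, so skipped transforms consume no
#' randomness. A final bilinear resize to the pipeline's `out_size` closes
#' the pipeline (masks re-binarised).
#'
#' @param image a preprocessed [us_image()] (mask present).
#' @param pipeline an [augmentation_pipeline()].
#' @param seed master integer seed.
#' @param image_index,view indices folded into the substream derivation,
#'   letting callers vary draws across images and paired views.
#' @return a list with `image` (the augmented [us_image()]) and
#'   `provenance` (ordered list of `list(id, params)` for the transforms
#'   actually applied).
#' @export
apply_pipeline <- function(image, pipeline, seed, image_index = 1L, view = 1L) {
  provenance <- list()
  for (s in pipeline$specs) {
    gate <- with_seed(substream_seed(seed, image_index, view, s$id, "gate"),
                      runif(1)) < s$probability
    if (!gate) next
    entry <- reg_get(s$id)
    cfg <- modifyList(entry$cfg, s$params)
    params <- with_seed(substream_seed(seed, image_index, view, s$id, "par"),
                        entry$draw(image, cfg))
    image <- tryCatch(entry$apply(image, params, cfg),
                      error = function(e)
                        stop(sprintf("transform %s failed: %s", s$id,
                                     conditionMessage(e)), call. = FALSE))
    provenance[[length(provenance) + 1]] <- list(id = s$id, params = params)
  }
  list(image = finalize_size(image, pipeline$out_size), provenance = provenance)
}

finalize_size <- function(image, out_size) {
  if (all(dim(image$pixels) == out_size)) return(image)
  image$pixels <- clip01(resize_bilinear(image$pixels, out_size[1], out_size[2]))
  image$mask <- (resize_bilinear(image$mask, out_size[1], out_size[2]) >= 0.5) * 1
  image$geometry <- NULL
  mask_zero(image)
}

#' Replay a logged augmentation
#'
#' Re-applies the transforms recorded in a provenance log with their logged
#' parameters, reproducing [apply_pipeline()]'s output bit-exactly.
#'
#' @param image the same source [us_image()].
#' @param pipeline the pipeline the provenance came from (supplies each
#'   transform's configuration and the final size).
#' @param provenance a provenance list from [apply_pipeline()].
#' @return the reconstructed [us_image()].
#' @export
replay_pipeline <- function(image, pipeline, provenance) {
  ids <- pipeline_ids(pipeline)
  for (p in provenance) {
    s <- pipeline$specs[[match(p$id, ids)]]
    entry <- reg_get(p$id)
    cfg <- modifyList(entry$cfg, s$params)
    image <- entry$apply(image, p$params, cfg)
  }
  finalize_size(image, pipeline$out_size)
}

#' Generate a positive pair for joint-embedding SSL
#'
#' Two independent pipeline draws on the same source image; the two views
#' share the master seed but use different view substreams.
#'
#' @inheritParams apply_pipeline
#' @return a list of class `positive_pair` with `view_a`, `view_b`
#'   ([us_image()]s) and `provenance` (per-view logs).
#' @export
positive_pair <- function(image, pipeline, seed, image_index = 1L) {
  a <- apply_pipeline(image, pipeline, seed, image_index, view = 1L)
  b <- apply_pipeline(image, pipeline, seed, image_index, view = 2L)
  structure(list(view_a = a$image, view_b = b$image,
                 provenance = list(view_a = a$provenance, view_b = b$provenance)),
            class = "positive_pair")
}

#' Remove one transform from a pipeline (leave-one-out ablation)
#'
#' @param pipeline an [augmentation_pipeline()].
#' @param omit_id id of the transform to drop (must be present).
#' @return a copy with that spec removed, order otherwise preserved, named
#'   `"<name>-minus-<id>"`.
#' @export
ablate <- function(pipeline, omit_id) {
  ids <- pipeline_ids(pipeline)
  if (!omit_id %in% ids)
    stop("transform ", omit_id, " is not in pipeline '", pipeline$name, "'",
         call. = FALSE)
  pipeline$specs <- pipeline$specs[ids != omit_id]
  pipeline$name <- paste0(pipeline$name, "-minus-", omit_id)
  pipeline
}

#' Write a pipeline to a YAML config
#'
#' @param pipeline an [augmentation_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_yaml <- function(pipeline, path) {
  obj <- list(name = pipeline$name,
              out_size = as.integer(pipeline$out_size),
              transforms = lapply(pipeline$specs, function(s)
                list(id = s$id, probability = s$probability, params = s$params)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a pipeline from a YAML config
#'
#' @param path a YAML file written by [write_pipeline_yaml()] (or
#'   hand-authored with the same keys).
#' @return an [augmentation_pipeline()].
#' @export
read_pipeline_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- lapply(obj$transforms, function(t)
    transform_spec(t$id, t$probability, t$params %||% list()))
  augmentation_pipeline(obj$name, specs,
                        out_size = as.numeric(obj$out_size %||% c(128, 128)))
}
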