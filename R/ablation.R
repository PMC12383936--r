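# Leave-one-out ablation harness: for a pipeline and a labelled dataset,
# scores the full pipeline and every single-omission variant with a linear
# probe under patient-grouped cross-validation, then runs the Friedman ->
# Wilcoxon -> Holm cascade to decide which transforms are contributory and
# assembles the distilled pipeline from them.

#' Radial-profile and histogram features of an ultrasound image
#'
#' The packaged handcrafted embedding: per-depth-band mean in-FOV intensity
#' (depth measured over the mask's nonzero rows), an in-FOV intensity
#' histogram, and two ray statistics of the lower half (brightest ray mean
#' and its ratio to the median ray) that pick up B-line rays.
#'
#' @param image an [us_image()].
#' @param n_depth number of depth bands.
#' @param n_bins number of histogram bins.
#' @return a numeric feature vector of length `n_depth + n_bins + 2`.
#' @export
radial_histogram_features <- function(image, n_depth = 8, n_bins = 8) {
  px <- image$pixels; mk <- image$mask
  rows <- which(rowSums(mk) > 0)
  prof <- vapply(rows, function(r) {
    sel <- mk[r, ] > 0
    mean(px[r, sel])
  }, numeric(1))
  band <- cut(seq_along(prof), n_depth, labels = FALSE)
  depth_feat <- vapply(seq_len(n_depth), function(b) mean(prof[band == b]),
                       numeric(1))
  depth_feat[is.na(depth_feat)] <- 0
  v <- px[mk > 0]
  hist_feat <- tabulate(pmin(floor(v * n_bins) + 1, n_bins), n_bins) / length(v)
  # per-ray means of the lower half: beam columns when the geometry is
  # known, else in-FOV image columns
  lower_means <- function() {
    if (!is.null(image$geometry)) {
      beam <- inverse_scan_convert(image)
      lo <- seq(ceiling(nrow(beam) * 0.45), nrow(beam))
      colMeans(beam[lo, , drop = FALSE])
    } else {
      lo <- rows[seq(ceiling(length(rows) * 0.45), length(rows))]
      cm <- colSums(px[lo, , drop = FALSE] * mk[lo, , drop = FALSE])
      cnt <- colSums(mk[lo, , drop = FALSE])
      (cm / pmax(cnt, 1))[cnt > 0]
    }
  }
  cm <- lower_means()
  ray_feat <- if (length(cm) == 0) c(0, 0)
              else c(max(cm), max(cm) / (stats::median(cm) + 1e-6))
  c(depth_feat, hist_feat, ray_feat)
}

#' Default pipeline-aware embedder
#'
#' Emulates, at desk scale, a feature extractor trained under a given
#' augmentation pipeline: augments the image once with the pipeline and
#' extracts [radial_histogram_features()] from the augmented view.
#' Deterministic given `seed`.
#'
#' @return a function `(image, pipeline, seed) -> numeric vector` for
#'   [run_leave_one_out()].
#' @export
default_embedder <- function() {
  function(image, pipeline, seed) {
    out <- apply_pipeline(image, pipeline, seed)
    radial_histogram_features(out$image)
  }
}

#' Compact oracle features of a phantom
#'
#' Four strongly class-informative statistics used by the planted-effect
#' harness: the brightest lower-half ray mean and its ratio to the median
#' ray (B-line signature), the fraction of near-anechoic in-FOV pixels
#' (effusion signature), and the in-FOV mean intensity.
#'
#' @param image an [us_image()].
#' @return a numeric vector of length 4.
#' @export
oracle_features <- function(image) {
  v <- image$pixels[image$mask > 0]
  cm <- if (!is.null(image$geometry)) {
    beam <- inverse_scan_convert(image)
    lo <- seq(ceiling(nrow(beam) * 0.45), nrow(beam))
    colMeans(beam[lo, , drop = FALSE])
  } else {
    rows <- which(rowSums(image$mask) > 0)
    lo <- rows[seq(ceiling(length(rows) * 0.45), length(rows))]
    cs <- colSums(image$pixels[lo, , drop = FALSE] * image$mask[lo, , drop = FALSE])
    cnt <- colSums(image$mask[lo, , drop = FALSE])
    (cs / pmax(cnt, 1))[cnt > 0]
  }
  c(max(cm), max(cm) / (stats::median(cm) + 1e-6), mean(v < 0.15), mean(v))
}

#' Oracle embedder with a planted contributory transform
#'
#' Returns an embedder whose features carry the class signal only while
#' `destroy_id` is part of the pipeline: when that transform is absent the
#' features are replaced by pure noise, synthetically recreating the
#' situation where omitting one transform destroys the learned
#' representation. Gaussian feature noise of `noise_sd` (relative to each
#' feature vector's spread) is always added.
#'
#' @param destroy_id transform id whose omission destroys the features.
#' @param noise_sd relative noise level on the intact features.
#' @param feature_fn base feature extractor (default [oracle_features()]).
#' @return a function `(image, pipeline, seed) -> numeric vector`.
#' @export
planted_embedder <- function(destroy_id, noise_sd = 0.1,
                             feature_fn = oracle_features) {
  function(image, pipeline, seed) {
    f <- feature_fn(image)
    s <- stats::sd(f) + 1e-8
    if (!destroy_id %in% pipeline_ids(pipeline)) {
      return(with_seed(seed, rnorm(length(f))))   # all signal destroyed
    }
    with_seed(seed, f + rnorm(length(f), 0, noise_sd * s))
  }
}

# ridge-regularised linear probe; returns scores for newdata
linear_probe_scores <- function(x_train, y_train, x_test, lambda = 1) {
  mu <- colMeans(x_train)
  sg <- apply(x_train, 2, sd)
  sg[sg < 1e-10] <- 1
  xt <- sweep(sweep(x_train, 2, mu), 2, sg, "/")
  xs <- sweep(sweep(x_test, 2, mu), 2, sg, "/")
  y <- y_train - mean(y_train)
  w <- solve(crossprod(xt) + lambda * diag(ncol(xt)), crossprod(xt, y))
  as.vector(xs %*% w)
}

# per-fold AUROC of the probe; NA for folds missing a class
fold_aucs <- function(features, y, folds) {
  vapply(seq_along(folds), function(f) {
    te <- folds[[f]]; tr <- setdiff(seq_along(y), te)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) return(NA_real_)
    sc <- linear_probe_scores(features[tr, , drop = FALSE], y[tr],
                              features[te, , drop = FALSE])
    auroc(sc, y[te])
  }, numeric(1))
}

# ordering convention for the distilled pipeline: ultrasound intensity
# transforms, then photometric jitter, then geometric, with crop-and-resize
# last (matches the published distilled sequence).
distill_order <- function(ids) {
  cls <- function(id) {
    if (id == "A00") return(4)
    if (id %in% c("B02", "B03", "B04", "B05", "B07", "B08", "B09")) return(1)
    if (id %in% c("A02", "A03", "A04", "A05")) return(2)
    3
  }
  ids[order(vapply(ids, cls, numeric(1)), match(ids, names(.table_prob)))]
}

#' Leave-one-out ablation analysis of an augmentation pipeline
#'
#' For the baseline pipeline and every single-omission ablation, computes
#' per-fold AUROC of a ridge linear probe on `embed_fn` features under
#' patient-grouped k-fold cross-validation, for each classification task.
#' Per task, a Friedman omnibus test across conditions gates post-hoc
#' Wilcoxon signed-rank comparisons of each ablation against the baseline,
#' Holm-corrected at family-wise level `alpha`. Transforms whose omission
#' significantly lowers AUROC on at least one task form the contributory
#' set, from which a distilled pipeline is assembled (intensity transforms
#' first, then photometric, then geometric, crop last).
#'
#' @param pipeline the baseline [augmentation_pipeline()].
#' @param dataset a `phantom_dataset` (or any list with `images` and a
#'   `manifest` containing `patient_id` and `label`).
#' @param embed_fn `function(image, pipeline, seed) -> numeric vector`;
#'   default [default_embedder()].
#' @param tasks named list; each task is `list(pos=, neg=)` label values.
#' @param k folds (default 10).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed master seed.
#' @return an object of class `ablation_report`; see [tidy.ablation_report()].
#' @export
run_leave_one_out <- function(pipeline, dataset, embed_fn = default_embedder(),
                              tasks = list(AB = list(pos = "B", neg = "A"),
                                           PE = list(pos = "effusion",
                                                     neg = "normal")),
                              k = 10, alpha = 0.05, seed = 1) {
  man <- dataset$manifest
  ids <- pipeline_ids(pipeline)
  conditions <- c(list(baseline = pipeline),
                  setNames(lapply(ids, function(id) ablate(pipeline, id)), ids))

  # embed every image under every condition
  feats <- lapply(names(conditions), function(cn) {
    pl <- conditions[[cn]]
    do.call(rbind, lapply(seq_along(dataset$images), function(i)
      embed_fn(dataset$images[[i]], pl, substream_seed(seed, cn, i, "embed"))))
  })
  names(feats) <- names(conditions)

  score_rows <- list(); summ_rows <- list(); fried_rows <- list()
  contributory <- character(0)
  for (tn in names(tasks)) {
    tk <- tasks[[tn]]
    sel <- which(man$label %in% c(tk$pos, tk$neg))
    if (length(unique(man$patient_id[sel])) < k) {
      warning("task ", tn, ": fewer than k patients; skipped")
      next
    }
    y <- as.integer(man$label[sel] == tk$pos)
    folds <- grouped_kfold(man$patient_id[sel], k,
                           seed = substream_seed(seed, tn, "folds"))
    mat <- vapply(names(conditions), function(cn)
      fold_aucs(feats[[cn]][sel, , drop = FALSE], y, folds),
      numeric(k))
    keep <- complete.cases(mat)
    if (sum(!keep) > 0)
      warning("task ", tn, ": ", sum(!keep),
              " fold(s) skipped for missing a class; k reduced to ", sum(keep))
    mat <- mat[keep, , drop = FALSE]
    if (nrow(mat) < 2) {
      warning("task ", tn, ": fewer than 2 usable folds; task skipped")
      next
    }
    ft <- friedman_test(mat)
    fried_rows[[tn]] <- tibble::tibble(task = tn, statistic = ft$statistic,
                                       p_value = ft$p_value, df = ft$df,
                                       n_folds = nrow(mat))
    for (cn in names(conditions)) {
      for (f in seq_len(nrow(mat)))
        score_rows[[length(score_rows) + 1]] <-
          tibble::tibble(task = tn, condition = cn, fold = f, auc = mat[f, cn])
    }
    wp <- rep(NA_real_, length(ids)); names(wp) <- ids
    decision <- rep("no-difference", length(ids)); names(decision) <- ids
    if (ft$p_value < alpha) {
      for (id in ids)
        wp[id] <- wilcoxon_signed_rank(mat[, id], mat[, "baseline"])$p_value
      rej <- holm_bonferroni(wp, alpha)
      for (j in seq_along(ids)) {
        id <- ids[j]
        if (rej[j]) {
          md <- median(mat[, id]) - median(mat[, "baseline"])
          decision[id] <- if (md < 0) "lower" else "higher"
          if (md < 0) contributory <- union(contributory, id)
        }
      }
    }
    for (cn in names(conditions)) {
      summ_rows[[length(summ_rows) + 1]] <- tibble::tibble(
        task = tn, condition = cn,
        omitted = if (cn == "baseline") "None" else cn,
        mean = mean(mat[, cn]), sd = sd(mat[, cn]),
        median = median(mat[, cn]),
        wilcoxon_p = if (cn == "baseline") NA_real_ else unname(wp[cn]),
        decision = if (cn == "baseline") NA_character_ else unname(decision[cn]))
    }
  }
  contributory <- distill_order(contributory)
  distilled <- if (length(contributory) > 0) {
    augmentation_pipeline(paste0(pipeline$name, "-distilled"),
                          lapply(contributory, function(id)
                            transform_spec(id, unname(.table_prob[id]))),
                          out_size = pipeline$out_size)
  } else NULL
  structure(list(scores = do.call(rbind, score_rows),
                 summary = do.call(rbind, summ_rows),
                 friedman = do.call(rbind, fried_rows),
                 contributory_set = contributory,
                 distilled = distilled,
                 alpha = alpha, k = k, seed = seed,
                 pipeline = pipeline$name),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("<ablation_report: pipeline '%s', alpha %.2f>\n", x$pipeline, x$alpha))
  print(x$friedman)
  cat("contributory set:",
      if (length(x$contributory_set)) paste(x$contributory_set, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}

#' Tidy an ablation report
#'
#' @param x an `ablation_report`.
#' @param ... unused.
#' @return a tibble with one row per task x condition: mean, sd, median
#'   fold AUROC, post-hoc Wilcoxon p-value and Holm decision.
#' @export
tidy.ablation_report <- function(x, ...) x$summary

#' One-row-per-task glance at an ablation report
#'
#' @param x an `ablation_report`.
#' @param ... unused.
#' @return a tibble with the Friedman omnibus results and the size of the
#'   contributory set.
#' @export
glance.ablation_report <- function(x, ...) {
  out <- x$friedman
  out$n_contributory <- length(x$contributory_set)
  out
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Boxplots of per-fold AUROC by condition
#'
#' @param object an `ablation_report`.
#' @param ... unused.
#' @return a ggplot object, one facet per task.
#' @export
autoplot.ablation_report <- function(object, ...) {
  df <- object$scores
  df$condition <- factor(df$condition, levels = unique(df$condition))
  condition <- auc <- NULL  # quiet R CMD check notes on aes() columns
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~task, ncol = 1) +
    ggplot2::labs(x = "omitted transform", y = "fold AUROC") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render an ablation report as a Markdown table
#'
#' @param report an `ablation_report`.
#' @return a character scalar of Markdown.
#' @export
report_markdown <- function(report) {
  s <- report$summary
  lines <- c(sprintf("### Leave-one-out ablation: %s", report$pipeline), "",
             "| Task | Omitted | Mean (std) | Median | Wilcoxon p | Decision |",
             "|------|---------|------------|--------|------------|----------|")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %.3f (%.3f) | %.3f | %s | %s |",
      s$task[i], s$omitted[i], s$mean[i], s$sd[i], s$median[i],
      ifelse(is.na(s$wilcoxon_p[i]), "-", sprintf("%.4f", s$wilcoxon_p[i])),
      ifelse(is.na(s$decision[i]), "-", s$decision[i])))
  }
  paste(lines, collapse = "\n")
}
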