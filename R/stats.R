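# Statistical machinery for the leave-one-out ablation analysis: grouped
# (patient-level) splitting, rank-based AUROC, the Friedman omnibus test,
# exact/approximate Wilcoxon signed-rank, and Holm-Bonferroni step-down
# control. The tests are implemented to the contracts used by the analysis
# (average-rank ties, exact sign enumeration for small samples); base R's
# friedman.test / wilcox.test serve as independent cross-checks in the test
# suite.

#' Patient-grouped k-fold assignment
#'
#' Every patient's images land in exactly one fold; fold patient-counts
#' differ by at most one. Deterministic given `seed`.
#'
#' @param patient_ids character vector, one entry per image.
#' @param k number of folds (at most the number of distinct patients).
#' @param seed integer seed for the patient shuffle.
#' @return a list of `k` integer vectors of image indices.
#' @export
grouped_kfold <- function(patient_ids, k, seed = 1) {
  pats <- unique(patient_ids)
  if (length(pats) < k)
    stop("need at least k distinct patients (", length(pats), " < ", k, ")",
         call. = FALSE)
  pats <- with_seed(seed, sample(pats))
  fold_of_pat <- setNames(rep_len(seq_len(k), length(pats)), pats)
  lapply(seq_len(k), function(f)
    unname(which(fold_of_pat[patient_ids] == f)))
}

#' Disjoint patient-grouped subsets
#'
#' Splits patients into `n_subsets` pairwise-disjoint subsets each holding
#' approximately `fraction` of the patients (floor/ceil balanced).
#'
#' @param patient_ids character vector, one entry per image.
#' @param fraction fraction of patients per subset.
#' @param n_subsets number of subsets; `n_subsets * fraction` must be <= 1.
#' @param seed integer seed.
#' @return a list of `n_subsets` integer vectors of image indices.
#' @export
grouped_subsets <- function(patient_ids, fraction, n_subsets, seed = 1) {
  if (n_subsets * fraction > 1 + 1e-9)
    stop("infeasible: n_subsets * fraction exceeds 1", call. = FALSE)
  pats <- unique(patient_ids)
  pats <- with_seed(seed, sample(pats))
  npat <- length(pats)
  cuts <- round(seq_len(n_subsets) * fraction * npat)
  sizes <- diff(c(0, cuts))
  if (any(sizes < 1)) stop("infeasible: empty subset requested", call. = FALSE)
  starts <- cumsum(c(0, head(sizes, -1)))
  lapply(seq_len(n_subsets), function(i) {
    sel <- pats[starts[i] + seq_len(sizes[i])]
    which(patient_ids %in% sel)
  })
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, counting ties as one half; equals the trapezoidal area
#' under the ROC curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or logical); both classes must be
#'   present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("auroc requires both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Friedman rank test for multiple dependent conditions
#'
#' Within-block average ranks with the standard tie correction; chi-square
#' upper-tail p with `k - 1` degrees of freedom. A fully tied matrix
#' returns statistic 0 and p = 1.
#'
#' @param score_matrix numeric matrix, `n` blocks (rows) by `k` conditions
#'   (columns).
#' @return a list with `statistic`, `p_value`, `df`.
#' @export
friedman_test <- function(score_matrix) {
  x <- as.matrix(score_matrix)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 conditions", call. = FALSE)
  rk <- t(apply(x, 1, rank))
  rbar <- colMeans(rk)
  stat_num <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  # tie correction: 1 - sum(t^3 - t) / (n k (k^2 - 1))
  tie_sum <- sum(apply(x, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C <= 0) return(list(statistic = 0, p_value = 1, df = k - 1))
  stat <- stat_num / C
  list(statistic = stat, p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
       df = k - 1)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' average-rank ties. The statistic is `min(W+, W-)`. For `m <= exact_max`
#' remaining pairs the two-sided p-value is computed exactly by enumerating
#' all `2^m` sign assignments; otherwise a normal approximation with tie
#' correction is used. If all differences are zero the result is flagged
#' degenerate with p = 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest `m` for which exact enumeration is used
#'   (default 12).
#' @return a list with `statistic` (`min(W+, W-)`), `w_plus`, `p_value`,
#'   `m` (nonzero pairs), `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    return(list(statistic = 0, w_plus = 0, p_value = 1, m = 0, degenerate = TRUE))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (m <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    wdist <- as.vector(signs %*% r)
    p <- 2 * min(mean(wdist <= w_plus), mean(wdist >= w_plus))
    p <- min(p, 1)
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = w, w_plus = w_plus, p_value = p, m = m, degenerate = FALSE)
}

#' Holm-Bonferroni step-down multiple-comparison control
#'
#' Sorts the p-values ascending and rejects while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure; decisions
#' are reported in the original order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise significance level (default 0.05).
#' @return logical vector of rejections, in input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0) return(logical(0))
  ord <- order(p_values)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) {
      reject[ord[i]] <- TRUE
    } else break
  }
  reject
}
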