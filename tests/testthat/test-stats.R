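# Statistical machinery: closed-form examples, independent enumeration
# oracles, and agreement with base R's implementations where they overlap.

# independent oracle: Wilcoxon signed-rank two-sided p by looping over all
# sign patterns as integer bitmasks (structurally different from the
# implementation's expand.grid enumeration)
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)[x != y]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  wvals <- numeric(2^m)
  for (b in 0:(2^m - 1)) {
    signs <- as.integer(intToBits(b))[1:m]
    wvals[b + 1] <- sum(r[signs == 1])
  }
  min(1, 2 * min(mean(wvals <= w_obs), mean(wvals >= w_obs)))
}

# independent oracle: Friedman statistic straight from its defining rank
# formula (no tie correction; used on tie-free inputs only)
oracle_friedman_stat <- function(x) {
  n <- nrow(x); k <- ncol(x)
  rk <- t(apply(x, 1, rank))
  12 * n / (k * (k + 1)) * sum((colMeans(rk) - (k + 1) / 2)^2)
}

test_that("grouped k-fold partitions patients with balanced counts", {
  ids <- rep(sprintf("p%02d", 1:10), each = 3)
  folds <- grouped_kfold(ids, 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(vapply(folds, length, numeric(1)) == 3))
  expect_equal(sort(unlist(folds)), seq_along(ids))

  ids23 <- sprintf("q%02d", 1:23)
  f23 <- grouped_kfold(ids23, 10, seed = 2)
  sizes <- sort(vapply(f23, length, numeric(1)))
  expect_true(all(sizes %in% c(2, 3)))
  expect_equal(sum(sizes), 23)

  # patient-disjointness
  ids_rep <- rep(sprintf("r%02d", 1:12), times = sample(1:4, 12, replace = TRUE))
  fr <- grouped_kfold(ids_rep, 4, seed = 3)
  pats <- lapply(fr, function(ix) unique(ids_rep[ix]))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(pats[[i]], pats[[j]]), 0)

  expect_error(grouped_kfold(c("a", "b"), 3), "k")
  expect_identical(grouped_kfold(ids, 10, seed = 7),
                   grouped_kfold(ids, 10, seed = 7))
})

test_that("grouped subsets are disjoint with the requested sizes", {
  ids <- sprintf("p%03d", 1:100)
  subs <- grouped_subsets(ids, 0.05, 20, seed = 1)
  expect_length(subs, 20)
  expect_true(all(vapply(subs, length, numeric(1)) == 5))
  expect_length(unique(unlist(subs)), 100)

  all_in <- grouped_subsets(ids, 1.0, 1, seed = 2)
  expect_length(all_in[[1]], 100)

  expect_error(grouped_subsets(ids, 0.3, 4), "infeasible")
  expect_identical(grouped_subsets(ids, 0.1, 5, seed = 9),
                   grouped_subsets(ids, 0.1, 5, seed = 9))
})

test_that("auroc matches closed forms, symmetry, and pROC", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")

  set.seed(4)
  for (i in 1:20) {
    s <- rnorm(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, 1 - y), 1 - auroc(s, y))
    expect_equal(auroc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("friedman test matches its defining formula and base R", {
  # three blocks each ranking the conditions identically
  m <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3, byrow = TRUE)
  ft <- friedman_test(m)
  expect_equal(ft$statistic, 6.0)
  expect_equal(ft$df, 2)

  tied <- matrix(0.7, 4, 3)
  expect_equal(friedman_test(tied)$statistic, 0)
  expect_equal(friedman_test(tied)$p_value, 1)

  set.seed(5)
  for (i in 1:25) {
    x <- matrix(rnorm(5 * 4), 5, 4)    # continuous: tie-free
    ft <- friedman_test(x)
    expect_equal(ft$statistic, oracle_friedman_stat(x), tolerance = 1e-12)
    bt <- friedman.test(x)
    expect_equal(ft$statistic, unname(bt$statistic), tolerance = 1e-10)
    expect_equal(ft$p_value, unname(bt$p.value), tolerance = 1e-10)
    # invariance under within-block monotone transforms
    expect_equal(friedman_test(exp(x))$statistic, ft$statistic)
  }
})

test_that("wilcoxon signed-rank matches the enumeration oracle and base R", {
  r <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.25)

  same <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  set.seed(6)
  for (i in 1:40) {
    m <- sample(3:8, 1)
    x <- rnorm(m); y <- rnorm(m)
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    bt <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(r$p_value, bt$p.value, tolerance = 1e-10)
  }
  # ties handled by average ranks, still matching the oracle
  for (i in 1:10) {
    m <- sample(4:8, 1)
    x <- sample(1:4, m, replace = TRUE); y <- sample(1:4, m, replace = TRUE)
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon normal approximation is close to exact near the boundary", {
  set.seed(7)
  x <- rnorm(13); y <- rnorm(13) - 0.5
  appr <- wilcoxon_signed_rank(x, y, exact_max = 12)$p_value
  exact <- wilcoxon_signed_rank(x, y, exact_max = 20)$p_value
  expect_lt(abs(appr - exact), 0.03)
})

test_that("holm-bonferroni step-down matches hand-computed decisions", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(holm_bonferroni(0.04, 0.05), TRUE)
  expect_equal(holm_bonferroni(0.06, 0.05), FALSE)
  # all small: everything rejected
  expect_equal(holm_bonferroni(c(0.001, 0.002, 0.003), 0.05), rep(TRUE, 3))
  # matches p.adjust-based decisions on random vectors
  set.seed(8)
  for (i in 1:20) {
    p <- runif(6)
    expect_equal(holm_bonferroni(p, 0.05), p.adjust(p, "holm") <= 0.05)
  }
})
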