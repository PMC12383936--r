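# Minimal 2-D orthogonal wavelet transform (Daubechies 4-tap, periodic
# boundary) plus the Birge-Massart coefficient-retention rule used by the
# wavelet-denoising transform. No wavelet package ships with the imaging
# stack this package targets, and the retention rule is part of the method,
# so both live here and are tested against reconstruction oracles.

# Daubechies D4 analysis filters (orthonormal)
.db4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db4_hi <- rev(.db4_lo) * c(1, -1, 1, -1)

# one periodic analysis step along columns of x: returns list(lo, hi),
# each with half the rows
dwt_step_cols <- function(x) {
  n <- nrow(x)
  lo <- matrix(0, n / 2, ncol(x))
  hi <- matrix(0, n / 2, ncol(x))
  for (k in 0:3) {
    idx <- ((2 * (seq_len(n / 2) - 1) + k) %% n) + 1
    lo <- lo + .db4_lo[k + 1] * x[idx, , drop = FALSE]
    hi <- hi + .db4_hi[k + 1] * x[idx, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# inverse of dwt_step_cols (periodic synthesis)
idwt_step_cols <- function(lo, hi) {
  n <- 2 * nrow(lo)
  out <- matrix(0, n, ncol(lo))
  for (k in 0:3) {
    idx <- ((2 * (seq_len(n / 2) - 1) + k) %% n) + 1
    out[idx, ] <- out[idx, , drop = FALSE] +
      .db4_lo[k + 1] * lo + .db4_hi[k + 1] * hi
  }
  out
}

#' Multi-level 2-D discrete wavelet transform
#'
#' Orthonormal Daubechies 4-tap filters with periodic boundary handling.
#' Dimensions must be divisible by `2^levels`.
#'
#' @param x numeric matrix.
#' @param levels decomposition depth.
#' @return a list with `approx` (coarsest approximation band) and `detail`,
#'   a list of length `levels`; `detail[[j]]` holds the three detail bands
#'   (`lh`, `hl`, `hh`) at level `j`, where `j = 1` is the **coarsest**.
#' @export
dwt2 <- function(x, levels = 3) {
  if (any(dim(x) %% 2^levels != 0))
    stop("image dimensions must be divisible by 2^levels", call. = FALSE)
  detail <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {          # lev 1 = finest
    s1 <- dwt_step_cols(a)
    ll_lh <- lapply(s1, function(m) dwt_step_cols(t(m)))
    a <- t(ll_lh$lo$lo)
    detail[[levels - lev + 1]] <- list(lh = t(ll_lh$lo$hi),
                                       hl = t(ll_lh$hi$lo),
                                       hh = t(ll_lh$hi$hi))
  }
  list(approx = a, detail = detail, levels = levels, dim = dim(x))
}

#' Inverse of [dwt2()]
#'
#' @param w a decomposition from [dwt2()].
#' @return the reconstructed matrix.
#' @export
idwt2 <- function(w) {
  a <- w$approx
  for (j in seq_len(w$levels)) {          # j 1 = coarsest
    d <- w$detail[[j]]
    lo <- idwt_step_cols(t(a), t(d$lh))
    hi <- idwt_step_cols(t(d$hl), t(d$hh))
    a <- idwt_step_cols(t(lo), t(hi))
  }
  a
}

#' Birge-Massart wavelet coefficient retention
#'
#' Keeps, at detail level `j` (1 = coarsest), only the `n_j` detail
#' coefficients of largest magnitude across the three orientation bands,
#' with `n_j = m / (j + 1)^alpha`; all other detail coefficients are zeroed.
#' `m` defaults to the number of coefficients in the coarsest approximation
#' band. Larger `alpha` discards more (denoising/compression regime).
#'
#' @param w a decomposition from [dwt2()].
#' @param alpha sparsity exponent (default 3).
#' @param m retention base; default `length(w$approx)`.
#' @return the thresholded decomposition.
#' @export
bm_threshold <- function(w, alpha = 3, m = NULL) {
  if (is.null(m)) m <- length(w$approx)
  for (j in seq_len(w$levels)) {
    n_j <- floor(m / (j + 1)^alpha)
    d <- w$detail[[j]]
    v <- c(d$lh, d$hl, d$hh)
    if (n_j >= length(v)) next
    if (n_j <= 0) {
      w$detail[[j]] <- lapply(d, function(b) b * 0)
      next
    }
    cut <- sort(abs(v), decreasing = TRUE)[n_j]
    w$detail[[j]] <- lapply(d, function(b) b * (abs(b) >= cut))
  }
  w
}
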