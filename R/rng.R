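#' Derive a deterministic substream seed
#'
#' Hashes an arbitrary tuple of atomic components into a 31-bit integer seed.
#' Used to give every (image, view, transform, purpose) combination its own
#' random substream so that removing one transform from a pipeline does not
#' shift the draws of the others.
#'
#' @param ... atomic components (coerced to character) identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "B00", "gate")
substream_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so surrounding code is unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
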