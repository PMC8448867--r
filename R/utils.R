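#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic stages of the pipeline (fold plans, permutation tests,
#' perturbation runs, the synthetic generator) draw their own seed from a
#' single master seed through this function, so a whole analysis is
#' reproducible bit-for-bit from one integer without the stages sharing a
#' random stream.
#'
#' @param seed Master seed (single integer).
#' @param n Number of sub-seeds to derive.
#' @return An integer vector of length `n`, each usable as a seed.
#' @export
#' @examples
#' spawn_seeds(1L, 3)
spawn_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), n >= 1)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# shared input checks -------------------------------------------------------

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  invisible(x)
}

assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
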