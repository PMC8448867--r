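#' Paired model comparison by permutation-thresholded signed-rank test
#'
#' Per-repetition CV losses from two models evaluated on the same fold plan
#' are paired, but the repetitions overlap in training data and are not
#' independent, so the usual signed-rank null distribution is unreliable.
#' The statistic is therefore thresholded against a within-pair label
#' permutation null: each pair's model labels are swapped independently with
#' probability one half and the statistic recomputed, which preserves the
#' dependence structure across repetitions while destroying any genuine
#' model difference.
#'
#' @name comparison
NULL

#' Wilcoxon signed-rank statistic on paired loss vectors
#'
#' The statistic is the sum of ranks of the positive differences `a - b`
#' among the non-zero differences (zero differences dropped, ties given mean
#' ranks — the standard conventions). Its centred form,
#' `W - m(m+1)/4` for `m` non-zero pairs, is symmetric about zero under
#' exchangeability and is what the two-sided permutation test uses.
#'
#' @param a,b Numeric vectors of equal length, paired elementwise.
#' @return List with `statistic` (W), `centered`, `n_nonzero`, and a
#'   `degenerate` flag set when every difference is zero (W defined as 0).
#' @export
signed_rank_statistic <- function(a, b) {
  stopifnot(length(a) == length(b), !anyNA(a), !anyNA(b))
  d <- a - b
  nz <- d != 0
  m <- sum(nz)
  if (m == 0)
    return(list(statistic = 0, centered = 0, n_nonzero = 0L,
                degenerate = TRUE))
  r <- rank(abs(d[nz]))
  W <- sum(r[d[nz] > 0])
  list(statistic = W, centered = W - m * (m + 1) / 4, n_nonzero = m,
       degenerate = FALSE)
}

# Null distribution of the centred statistic under within-pair label swaps.
# Ranks of |d| are invariant under sign flips, so only the sign pattern is
# resampled; computed in chunks to bound memory at large permutation counts.
permute_centered_stats <- function(d, n_permutations) {
  nz <- d != 0
  m <- sum(nz)
  r <- rank(abs(d[nz]))
  offset <- m * (m + 1) / 4
  out <- numeric(n_permutations)
  done <- 0
  chunk <- max(1, min(n_permutations, floor(2e6 / max(m, 1))))
  while (done < n_permutations) {
    b <- min(chunk, n_permutations - done)
    flips <- matrix(stats::runif(m * b) < 0.5, m, b)   # TRUE = keep a > b sign
    out[done + seq_len(b)] <- drop(crossprod(flips, r)) - offset
    done <- done + b
  }
  out
}

#' Paired within-pair permutation test of two loss vectors
#'
#' Builds the null by independently swapping each pair's labels with
#' probability 1/2 and recomputing the signed-rank statistic; the two-sided
#' p-value compares absolute centred statistics with add-one smoothing,
#' `p = (1 + #{|null| >= |obs|}) / (1 + n_permutations)`, so p never
#' underruns the permutation floor `1/(n_permutations + 1)`.
#'
#' @param a,b Paired per-repetition loss vectors (same fold plan).
#' @param n_permutations Number of label permutations (default 10000,
#'   minimum 999).
#' @param seed Seed; the test is deterministic given it.
#' @param label_a,label_b Model labels carried into the result.
#' @return Object of class `comparison_result` with the observed statistic,
#'   the permutation p-value and bookkeeping fields.
#' @export
paired_permutation_test <- function(a, b, n_permutations = 10000, seed,
                                    label_a = "model_a", label_b = "model_b") {
  if (n_permutations < 999)
    stop("use at least 999 permutations", call. = FALSE)
  obs <- signed_rank_statistic(a, b)
  if (obs$degenerate) {
    p <- 1
  } else {
    d <- a - b
    null_c <- withr::with_seed(as.integer(seed),
                               permute_centered_stats(d, n_permutations))
    p <- (1 + sum(abs(null_c) >= abs(obs$centered) - 1e-9)) /
      (1 + n_permutations)
  }
  structure(list(model_a = label_a, model_b = label_b,
                 statistic = obs$statistic, centered = obs$centered,
                 n_nonzero = obs$n_nonzero, degenerate = obs$degenerate,
                 p_value = p, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: W = %.1f, permutation p = %.4g (%d permutations)\n",
              x$model_a, x$model_b, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Familywise error adjustment over a family of comparisons
#'
#' Bonferroni by default (transparent and valid under any dependence); a
#' max-statistic permutation adjustment for the common all-models-vs-one-
#' reference family is available through [fwe_maxT()].
#'
#' @param results List of `comparison_result` objects forming one family.
#' @param alpha Familywise significance level (default 0.05).
#' @param method `"bonferroni"` or `"holm"`.
#' @return Data frame with one row per comparison: labels, statistic, raw and
#'   adjusted p-values, and a `significant` flag (`adjusted p < alpha`).
#' @export
fwe_adjust <- function(results, alpha = 0.05, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (length(results) == 0)
    return(data.frame(model_a = character(0), model_b = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  p <- vapply(results, `[[`, 0, "p_value")
  p_adj <- stats::p.adjust(p, method = method)
  data.frame(
    model_a = vapply(results, `[[`, "", "model_a"),
    model_b = vapply(results, `[[`, "", "model_b"),
    statistic = vapply(results, `[[`, 0, "statistic"),
    p_value = p, p_adjusted = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE)
}

#' Max-statistic permutation familywise adjustment
#'
#' For a family of paired comparisons sharing one fold plan (e.g. every
#' model against the null), a single set of within-pair label swaps is
#' applied jointly to all comparisons and the maximum absolute centred
#' statistic across the family forms the null; each comparison's adjusted
#' p-value is its observed statistic's tail probability under that maximum.
#' Less conservative than Bonferroni under positive dependence.
#'
#' @param pairs Named list; each element a list with vectors `a` and `b`.
#' @param n_permutations Number of joint permutations.
#' @param seed Seed.
#' @param alpha Familywise level.
#' @return Data frame as in [fwe_adjust()] (with `p_value` the unadjusted
#'   per-comparison permutation p under the same joint swaps).
#' @export
fwe_maxT <- function(pairs, n_permutations = 10000, seed, alpha = 0.05) {
  stopifnot(length(pairs) >= 1, !is.null(names(pairs)))
  D <- vapply(pairs, function(p) p$a - p$b, numeric(length(pairs[[1]]$a)))
  n_rep <- nrow(D)
  obs <- apply(D, 2, function(d) signed_rank_statistic(d, numeric(n_rep)))
  obs_c <- vapply(obs, `[[`, 0, "centered")
  nulls <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      keep <- stats::runif(n_rep) < 0.5
      vapply(seq_len(ncol(D)), function(j) {
        d <- D[, j]
        nz <- d != 0
        m <- sum(nz)
        if (m == 0) return(0)
        r <- rank(abs(d[nz]))
        sum(r[keep[nz] == (d[nz] > 0)]) - m * (m + 1) / 4
      }, 0)
    }, numeric(ncol(D)))
  })
  nulls <- matrix(nulls, ncol = n_permutations)
  max_null <- apply(abs(nulls), 2, max)
  p_adj <- vapply(obs_c, function(o)
    (1 + sum(max_null >= abs(o) - 1e-9)) / (1 + n_permutations), 0)
  p_raw <- vapply(seq_along(obs_c), function(j)
    (1 + sum(abs(nulls[j, ]) >= abs(obs_c[j]) - 1e-9)) / (1 + n_permutations), 0)
  data.frame(
    model_a = names(pairs), model_b = "reference",
    statistic = vapply(obs, `[[`, 0, "statistic"),
    p_value = p_raw, p_adjusted = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE)
}
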