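#' Model interpretation by data perturbation
#'
#' PLS component weights are awkward to interpret directly (several
#' components, arbitrary component signs), so influence is estimated by
#' perturbing the data instead: random subsets of the predictors are
#' shuffled across patients, the *fixed* fitted model predicts from each
#' perturbed design, and each predictor's influence weight is the mass
#' univariate Pearson correlation between its (perturbed) values and the
#' resulting predictions over the pooled patients-by-iterations sample.
#' Coefficients are never refit: the procedure reads out relationships the
#' model has already encoded.
#'
#' @name interpretation
NULL

#' Perturbation-derived influence weights
#'
#' Each iteration selects every variable independently with probability
#' `inclusion_p` and shuffles the selected variables' values across patients
#' (a within-variable permutation, preserving each marginal); unselected
#' variables keep their empirical values. All `n_patients * n_iterations`
#' rows are pooled and each variable's weight is the correlation between its
#' column and the predicted response in that pooled sample.
#'
#' @param model A `fitted_model` (its coefficients are held fixed).
#' @param X Numeric matrix of empirical predictors with column names
#'   matching the model's variables (e.g. `cohort_design(x, spec$blocks)`).
#' @param n_iterations Perturbation iterations (default 1000).
#' @param inclusion_p Per-variable selection probability (default 0.5).
#' @param seed Seed; the weights are deterministic given it.
#' @param perturb `"shuffle"` (default; permute values across patients) or
#'   `"resample"` (bootstrap resample with replacement).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `influence_weights`: `variable_ids`, `weights`
#'   (one correlation in \[-1, 1\] per variable), and the run parameters.
#' @export
perturb_and_weigh <- function(model, X, n_iterations = 1000,
                              inclusion_p = 0.5, seed,
                              perturb = c("shuffle", "resample"),
                              cor_method = c("pearson", "spearman")) {
  perturb <- match.arg(perturb)
  cor_method <- match.arg(cor_method)
  stopifnot(inherits(model, "fitted_model"), n_iterations >= 1,
            inclusion_p >= 0, inclusion_p <= 1)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  pooled_X <- matrix(NA_real_, n * n_iterations, p,
                     dimnames = list(NULL, colnames(X)))
  pooled_pred <- numeric(n * n_iterations)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iterations)) {
      Xi <- X
      sel <- which(stats::runif(p) < inclusion_p)
      for (j in sel) {
        Xi[, j] <- if (perturb == "shuffle") Xi[sample.int(n), j]
                   else Xi[sample.int(n, replace = TRUE), j]
      }
      rows <- (it - 1) * n + seq_len(n)
      pooled_X[rows, ] <- Xi
      pooled_pred[rows] <- predict(model, Xi)
    }
  })
  w <- vapply(seq_len(p), function(j) {
    xj <- pooled_X[, j]
    if (stats::sd(xj) == 0 || stats::sd(pooled_pred) == 0) {
      warning(sprintf("zero-variance pooled column '%s': weight set to 0",
                      colnames(X)[j]), call. = FALSE)
      return(0)
    }
    stats::cor(xj, pooled_pred, method = cor_method)
  }, 0)
  structure(list(variable_ids = colnames(X),
                 weights = stats::setNames(w, colnames(X)),
                 n_iterations = as.integer(n_iterations),
                 inclusion_p = inclusion_p, perturb = perturb,
                 cor_method = cor_method, seed = as.integer(seed)),
            class = "influence_weights")
}

#' @export
print.influence_weights <- function(x, ...) {
  cat(sprintf("<influence_weights> %d variables, %d iterations (inclusion p = %.2f)\n",
              length(x$weights), x$n_iterations, x$inclusion_p))
  top <- sort(abs(x$weights), decreasing = TRUE)
  top <- names(top)[seq_len(min(5, length(top)))]
  for (v in top) cat(sprintf("  %-16s %+.3f\n", v, x$weights[[v]]))
  invisible(x)
}

#' Stability of the perturbation weights across repetitions
#'
#' Repeats [perturb_and_weigh()] with independent sub-seeds and returns the
#' minimum pairwise Pearson correlation between the resulting weight
#' vectors — the check that the chosen iteration count yields consistent
#' influence estimates.
#'
#' @param model,X As in [perturb_and_weigh()].
#' @param n_runs Number of independent repetitions (>= 2; default 10).
#' @param n_iterations Iterations per repetition (default 1000).
#' @param seed Master seed; sub-seeds are spawned from it.
#' @param ... Passed on to [perturb_and_weigh()].
#' @return Minimum pairwise correlation (single number) with attributes
#'   `correlations` (full matrix) and `weights` (variables x runs matrix).
#' @export
stability_check <- function(model, X, n_runs = 10, n_iterations = 1000,
                            seed, ...) {
  stopifnot(n_runs >= 2)
  sub <- spawn_seeds(seed, n_runs)
  W <- vapply(sub, function(s)
    perturb_and_weigh(model, X, n_iterations = n_iterations, seed = s,
                      ...)$weights,
    numeric(ncol(X)))
  C <- stats::cor(W)
  structure(min(C[upper.tri(C)]), correlations = C, weights = W)
}

#' Proxy-region analysis of a lesion-load column
#'
#' Lesion anatomy makes region loads strongly inter-correlated, so a region
#' can carry a counter-intuitive positive influence weight simply because
#' damage there implies *sparing* of regions whose damage predicts poor
#' response. This analysis correlates the target region's load column with
#' every other region's column, and then correlates that vector with the
#' corresponding influence weights: a strong summary correlation indicates
#' the target's weight is a proxy for the lesion covariance structure rather
#' than a direct effect.
#'
#' @param loads A `lesion_load_matrix` or a patients x regions numeric
#'   matrix with region column names.
#' @param target_region Region id of the target column.
#' @param weights Optional `influence_weights` (or named numeric vector)
#'   covering the loads' regions; when supplied the summary correlation is
#'   computed.
#' @return List with `correlations` (named vector over the other regions,
#'   the target itself excluded) and `summary_correlation` (or `NA` when no
#'   weights are given).
#' @export
proxy_region_analysis <- function(loads, target_region, weights = NULL) {
  M <- if (inherits(loads, "lesion_load_matrix")) loads$values else as.matrix(loads)
  if (!target_region %in% colnames(M))
    stop(sprintf("region '%s' not present in the load matrix", target_region),
         call. = FALSE)
  tcol <- M[, target_region]
  if (stats::sd(tcol) == 0)
    stop(sprintf("region '%s' has zero load variance", target_region),
         call. = FALSE)
  others <- setdiff(colnames(M), target_region)
  cors <- vapply(others, function(rr) {
    if (stats::sd(M[, rr]) == 0) NA_real_ else stats::cor(tcol, M[, rr])
  }, 0)
  summary_cor <- NA_real_
  if (!is.null(weights)) {
    w <- if (inherits(weights, "influence_weights")) weights$weights else weights
    covered <- intersect(others, names(w))
    if (length(covered) < 3)
      stop("weights do not cover the load matrix's regions", call. = FALSE)
    ok <- covered[!is.na(cors[covered])]
    summary_cor <- stats::cor(cors[ok], w[ok])
  }
  list(correlations = cors, summary_correlation = summary_cor)
}

#' Ranked influence-weight table
#'
#' @param weights An `influence_weights` object.
#' @param manifest Optional region manifest data frame (`region_id`,
#'   `atlas_id`, `n_voxels`) used to annotate lesion variables.
#' @param by Rank by `"signed"` weight (default) or by `"abs"`olute weight,
#'   descending.
#' @return Data frame `variable_id`, `weight`, `rank` (+ atlas columns when
#'   a manifest is given), one row per model variable.
#' @export
weight_report <- function(weights, manifest = NULL, by = c("signed", "abs")) {
  by <- match.arg(by)
  w <- weights$weights
  if (length(w) == 0)
    return(data.frame(variable_id = character(0), weight = numeric(0),
                      rank = integer(0)))
  ord <- if (by == "signed") order(w, decreasing = TRUE)
         else order(abs(w), decreasing = TRUE)
  out <- data.frame(variable_id = names(w)[ord], weight = unname(w)[ord],
                    rank = seq_along(w), stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    out <- merge(out, manifest, by.x = "variable_id", by.y = "region_id",
                 all.x = TRUE, sort = FALSE)
    out <- out[order(out$rank), ]
    rownames(out) <- NULL
  }
  out
}
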