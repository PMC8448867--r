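#' Repeated k-fold cross-validation with shared fold plans
#'
#' Every model configuration is evaluated on the *same* repeated partitions
#' of the cohort, so per-repetition losses are paired across models and can
#' be compared with paired tests. Each repetition partitions patients into k
#' folds of near-equal size; all fitting — including z-scoring and any
#' component selection — is confined to the training folds.
#'
#' @name evaluation
NULL

#' Build a repeated k-fold plan
#'
#' @param n_patients Number of patients.
#' @param k Folds per repetition (default 10).
#' @param n_repetitions Number of repetitions (default 1000).
#' @param seed Seed; the plan is reproducible bit-for-bit from it.
#' @return Object of class `fold_plan` with an `assignments` matrix
#'   (`n_repetitions` x `n_patients`, entries in `1:k`).
#' @export
make_fold_plan <- function(n_patients, k = 10, n_repetitions = 1000, seed) {
  if (k > n_patients)
    stop("k must not exceed the number of patients", call. = FALSE)
  stopifnot(k >= 2, n_repetitions >= 1)
  sizes <- rep(n_patients %/% k, k)
  extra <- n_patients %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  fold_of_slot <- rep(seq_len(k), times = sizes)
  assignments <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_repetitions), function(r) {
      a <- integer(n_patients)
      a[sample.int(n_patients)] <- fold_of_slot
      a
    }, integer(n_patients)))
  })
  structure(list(n_patients = n_patients, k = k,
                 n_repetitions = n_repetitions, seed = as.integer(seed),
                 assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d repetitions of %d-fold CV over %d patients (seed %d)\n",
              x$n_repetitions, x$k, x$n_patients, x$seed))
  invisible(x)
}

#' Cross-validate one model configuration
#'
#' For each repetition of the plan, out-of-fold predictions for all patients
#' are pooled and a single mean squared error against the observed responses
#' is recorded (its square root is kept alongside). Pooling predictions
#' before averaging — rather than averaging per-fold losses — is the fixed
#' convention here; with near-equal fold sizes the two differ negligibly.
#'
#' @param x An `anomia_cohort`.
#' @param spec A `model_spec` (use `model_spec(NULL)` for the null model).
#' @param plan A `fold_plan` over the same number of patients.
#' @param standardize_scope Where the predictor z-scoring statistics come
#'   from. `"cohort"` (default) scales each predictor once on the whole
#'   cohort before the folds are cut, the usual "standardise prior to entry
#'   into models" convention, which keeps z-values of sparse bounded
#'   predictors (e.g. lesion loads damaged in one patient) within
#'   `sqrt(n - 1)`. `"training"` recomputes the statistics inside every
#'   training fold — strictly leakage-free, but a held-out patient can then
#'   sit tens of training sds out on a sparse column and dominate the loss.
#'   Response centring (the model intercept) always uses the training fold
#'   only.
#' @return Object of class `cv_result`: `label`, `mse` and `rmse`
#'   per-repetition vectors, `predictions` (repetitions x patients matrix of
#'   out-of-fold predictions), and the plan's identifying fields.
#' @export
cross_validate <- function(x, spec, plan,
                           standardize_scope = c("cohort", "training")) {
  standardize_scope <- match.arg(standardize_scope)
  stopifnot(inherits(x, "anomia_cohort"), inherits(spec, "model_spec"),
            inherits(plan, "fold_plan"))
  n <- n_patients(x)
  if (plan$n_patients != n)
    stop("fold plan and cohort disagree on the number of patients",
         call. = FALSE)
  y <- x$response
  is_null_model <- length(spec$blocks) == 0
  X <- if (!is_null_model) cohort_design(x, spec$blocks)
  Z <- if (!is_null_model && standardize_scope == "cohort")
    standardize(X)$values
  preds <- matrix(NA_real_, plan$n_repetitions, n,
                  dimnames = list(NULL, x$patient_ids))
  for (r in seq_len(plan$n_repetitions)) {
    fold <- plan$assignments[r, ]
    for (f in seq_len(plan$k)) {
      te <- fold == f
      tr <- !te
      if (is_null_model) {
        preds[r, te] <- mean(y[tr])
      } else {
        ncomp <- min(spec$ncomp, sum(tr) - 1, ncol(X))
        if (standardize_scope == "cohort") {
          Ztr <- Z[tr, , drop = FALSE]
          if (spec$select_ncomp)
            ncomp <- select_ncomp_inner(Ztr, y[tr], ncomp)
          fit <- fit_pls(Ztr, y[tr], ncomp)
          preds[r, te] <- predict(fit, Z[te, , drop = FALSE])
        } else {
          Xtr <- X[tr, , drop = FALSE]
          if (spec$select_ncomp)
            ncomp <- select_ncomp_inner(Xtr, y[tr], ncomp)
          z_train <- standardize(Xtr)
          scl <- ifelse(z_train$scale > 0, z_train$scale, 1)
          Xte <- sweep(sweep(X[te, , drop = FALSE], 2, z_train$center, "-"),
                       2, scl, "/")
          Xte[, z_train$scale == 0] <- 0
          fit <- fit_pls(z_train$values, y[tr], ncomp)
          preds[r, te] <- predict(fit, Xte)
        }
      }
    }
  }
  err2 <- sweep(preds, 2, y, "-")^2
  mse <- rowMeans(err2)
  structure(list(label = spec$label, spec = spec, mse = mse,
                 rmse = sqrt(mse), predictions = preds,
                 plan_seed = plan$seed, k = plan$k,
                 n_repetitions = plan$n_repetitions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: median MSE %.2f (IQR %.2f) over %d x %d-fold CV\n",
              x$label, stats::median(x$mse), stats::IQR(x$mse),
              x$n_repetitions, x$k))
  invisible(x)
}

#' Summarise a set of cross-validation results as a performance table
#'
#' One row per model: median and inter-quartile range of the per-repetition
#' MSE (and RMSE), matching the convention of reporting skewed CV losses by
#' median/IQR rather than mean/sd.
#'
#' @param results List of `cv_result` objects.
#' @return A data frame with columns `model`, `median_mse`, `iqr_mse`,
#'   `median_rmse`, `iqr_rmse`.
#' @export
cv_table <- function(results) {
  data.frame(
    model = vapply(results, `[[`, "", "label"),
    median_mse = vapply(results, function(r) stats::median(r$mse), 0),
    iqr_mse = vapply(results, function(r) stats::IQR(r$mse), 0),
    median_rmse = vapply(results, function(r) stats::median(r$rmse), 0),
    iqr_rmse = vapply(results, function(r) stats::IQR(r$rmse), 0),
    stringsAsFactors = FALSE)
}
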