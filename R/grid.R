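#' Run the all-combinations model grid
#'
#' The headline analysis: every non-empty combination of the four predictor
#' blocks (therapy hours, initial severity, demographics, lesion loads) plus
#' the group-mean null model is evaluated under repeated k-fold
#' cross-validation on one shared fold plan; each model is compared to the
#' null by the permutation-thresholded signed-rank test with familywise
#' error control; and the best model (lowest median MSE) is summarised by
#' its mean out-of-fold predictions against the empirical responses, with a
#' bootstrap confidence interval on their correlation, plus
#' perturbation-derived influence weights.
#'
#' @param x An `anomia_cohort`, or a `synthetic_cohort`, or a
#'   `generator_config` (simulated on the fly).
#' @param combos List of character vectors of block names; default all 15
#'   non-empty subsets of `c("hours", "initial_severity", "demographics",
#'   "lesions")`. The null model is always added.
#' @param n_repetitions,k Cross-validation parameters (defaults 1000 and 10).
#' @param ncomp PLS components per model (default 2).
#' @param n_permutations Permutations per model-vs-null comparison
#'   (default 10000).
#' @param alpha Familywise significance level (default 0.05).
#' @param fwe_method `"bonferroni"` (default) or `"maxT"` (joint
#'   max-statistic permutation over the family).
#' @param n_boot Bootstrap resamples for the predicted-vs-empirical
#'   correlation CI (default 2000, percentile method).
#' @param interpret_iterations Perturbation iterations for the best model's
#'   influence weights (default 1000; set 0 to skip interpretation).
#' @param seed Master seed; every stochastic stage draws a sub-seed from it.
#' @param outdir Optional output directory; when given, all tables are
#'   written as CSV plus a JSON run manifest, deterministically (two runs
#'   with the same seed produce byte-identical files).
#' @return List with `table` (performance table, null row first),
#'   `comparisons` (vs-null data frame), `best_model` label,
#'   `predictions` (patient, empirical, predicted), `prediction_cor`
#'   (estimate + CI), `weights` (influence weights of the best model or
#'   `NULL`), `plan`, and `seed`.
#' @export
run_grid <- function(x,
                     combos = default_block_combos(),
                     n_repetitions = 1000, k = 10, ncomp = 2,
                     n_permutations = 10000, alpha = 0.05,
                     fwe_method = c("bonferroni", "maxT"),
                     n_boot = 2000, interpret_iterations = 1000,
                     seed = 1, outdir = NULL) {
  fwe_method <- match.arg(fwe_method)
  if (inherits(x, "generator_config")) x <- simulate_cohort(x)
  coh <- if (inherits(x, "synthetic_cohort")) x$cohort else x
  stopifnot(inherits(coh, "anomia_cohort"))
  seeds <- spawn_seeds(seed, 3 + length(combos))
  plan <- make_fold_plan(n_patients(coh), k = k,
                         n_repetitions = n_repetitions, seed = seeds[1])
  specs <- c(list(model_spec(NULL)),
             lapply(combos, model_spec, ncomp = ncomp))
  results <- lapply(specs, function(sp) cross_validate(coh, sp, plan))
  names(results) <- vapply(results, `[[`, "", "label")
  tab <- cv_table(results)

  null_mse <- results[["null"]]$mse
  model_labels <- setdiff(names(results), "null")
  if (fwe_method == "bonferroni") {
    comps <- lapply(seq_along(model_labels), function(i)
      paired_permutation_test(results[[model_labels[i]]]$mse, null_mse,
                              n_permutations = n_permutations,
                              seed = seeds[3 + i],
                              label_a = model_labels[i], label_b = "null"))
    comparisons <- fwe_adjust(comps, alpha = alpha)
  } else {
    pairs <- lapply(results[model_labels],
                    function(r) list(a = r$mse, b = null_mse))
    comparisons <- fwe_maxT(pairs, n_permutations = n_permutations,
                            seed = seeds[4], alpha = alpha)
    comparisons$model_b <- "null"
  }

  best <- model_labels[which.min(tab$median_mse[match(model_labels, tab$model)])]
  mean_pred <- colMeans(results[[best]]$predictions)
  pred_df <- data.frame(patient_id = coh$patient_ids,
                        empirical = coh$response,
                        predicted = mean_pred,
                        stringsAsFactors = FALSE)
  prediction_cor <- cor_with_boot_ci(pred_df$empirical, pred_df$predicted,
                                     n_boot = n_boot, seed = seeds[2],
                                     alpha = alpha)

  weights <- NULL
  if (interpret_iterations > 0) {
    best_spec <- results[[best]]$spec
    fitted <- fit_model(coh, best_spec)
    weights <- perturb_and_weigh(fitted, cohort_design(coh, best_spec$blocks),
                                 n_iterations = interpret_iterations,
                                 seed = seeds[3])
  }

  out <- list(table = tab, comparisons = comparisons, best_model = best,
              predictions = pred_df, prediction_cor = prediction_cor,
              weights = weights, plan = plan, seed = as.integer(seed),
              results = results)
  if (!is.null(outdir)) write_grid_report(out, outdir, coh)
  out
}

#' Default block combinations of the model grid
#'
#' All 15 non-empty subsets of the four predictor blocks, ordered by subset
#' size then lexicographically, so the grid report has a stable row order.
#'
#' @return List of character vectors.
#' @export
default_block_combos <- function() {
  blocks <- c("hours", "initial_severity", "demographics", "lesions")
  combos <- list()
  for (m in 1:4)
    combos <- c(combos, utils::combn(blocks, m, simplify = FALSE))
  combos
}

#' Pearson correlation with a percentile bootstrap confidence interval
#'
#' @param x,y Numeric vectors.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed.
#' @param alpha 1 - confidence level (default 0.05 for a 95% CI).
#' @return List `estimate`, `ci_lower`, `ci_upper`, `n_boot`; the estimate
#'   is `NA` (with both bounds `NA`) when either input has zero variance,
#'   as happens for the null model's constant predictions.
#' @export
cor_with_boot_ci <- function(x, y, n_boot = 2000, seed, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, n_boot = as.integer(n_boot)))
  est <- stats::cor(x, y)
  n <- length(x)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, 0)
  })
  qs <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(estimate = est, ci_lower = qs[1], ci_upper = qs[2],
       n_boot = as.integer(n_boot))
}

# internal: write the grid report deterministically
write_grid_report <- function(out, outdir, coh) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$table, file.path(outdir, "performance_table.csv"),
                   row.names = FALSE)
  utils::write.csv(out$comparisons, file.path(outdir, "comparisons_vs_null.csv"),
                   row.names = FALSE)
  utils::write.csv(out$predictions,
                   file.path(outdir, "best_model_predictions.csv"),
                   row.names = FALSE)
  if (!is.null(out$weights))
    utils::write.csv(weight_report(out$weights),
                     file.path(outdir, "best_model_weights.csv"),
                     row.names = FALSE)
  manifest <- list(
    package = "anomiaPLS",
    package_version = as.character(utils::packageVersion("anomiaPLS")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = out$seed,
    fold_plan = list(k = out$plan$k, n_repetitions = out$plan$n_repetitions,
                     seed = out$plan$seed),
    n_patients = length(coh$patient_ids),
    best_model = out$best_model,
    prediction_cor = out$prediction_cor)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
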