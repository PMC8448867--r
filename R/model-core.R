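#' PLS prognostic models and the group-mean null model
#'
#' Models are fit on z-scored predictors with the response centred but not
#' scaled; where the z-scoring statistics come from during cross-validation
#' (whole cohort vs training fold) is an explicit evaluation option, see
#' [cross_validate()]. Partial least squares (PLS) regression
#' extracts latent components that maximise covariance with the response,
#' which keeps fits stable when predictors are many and collinear — the
#' typical situation for atlas-derived lesion loads in a small cohort. The
#' null model predicts every patient's response as the training-group mean
#' and is the baseline any prognostic model must beat.
#'
#' @name model-core
NULL

#' Z-score columns using training-sample statistics
#'
#' Each column of `newdata` is transformed by `(x - train_mean) / train_sd`
#' where the mean and sd (sample convention, n-1 denominator) come from
#' `train`. Columns constant in the training sample (sd 0) map to all zeros,
#' so adding an uninformative constant predictor never changes a model.
#'
#' @param train Numeric matrix the statistics are computed on (>= 2 rows).
#' @param newdata Numeric matrix to transform; defaults to `train`.
#' @return List with `values` (transformed `newdata`), `center` and `scale`.
#' @export
standardize <- function(train, newdata = train) {
  assert_matrix(train); assert_matrix(newdata)
  stopifnot(nrow(train) >= 2, ncol(train) == ncol(newdata))
  mu <- colMeans(train)
  sd <- sqrt(colSums(sweep(train, 2, mu, "-")^2) / (nrow(train) - 1))
  scl <- ifelse(sd > 0, sd, 1)
  out <- sweep(sweep(newdata, 2, mu, "-"), 2, scl, "/")
  out[, sd == 0] <- 0
  list(values = out, center = mu, scale = sd)
}

#' Fit a univariate-response PLS regression (NIPALS)
#'
#' Predictors are used as given (callers standardize first); the response is
#' centred internally. Component extraction stops early if the residual
#' covariance with the response vanishes, so a constant response yields a
#' zero coefficient vector, and requesting the full rank of `X` reproduces
#' ordinary least squares. Coefficients are returned in original-variable
#' space so prediction is a single affine map.
#'
#' @param X Numeric predictor matrix (n x p), typically z-scored.
#' @param y Numeric response of length n.
#' @param ncomp Number of latent components; must satisfy
#'   `ncomp <= min(n - 1, p)`.
#' @return An object of class `pls_fit` with `coefficients`, `intercept`,
#'   `ncomp` (requested) and `ncomp_used`, plus the NIPALS loadings.
#' @export
fit_pls <- function(X, y, ncomp) {
  assert_matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, !anyNA(y), !anyNA(X))
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop(sprintf("ncomp must be in [1, min(n - 1, p)] = [1, %d]",
                 min(n - 1, p)), call. = FALSE)
  ybar <- mean(y)
  xbar <- colMeans(X)
  E <- sweep(X, 2, xbar, "-")
  f <- y - ybar
  tol <- 1e-12 * max(1, sum(E^2), sum(f^2))
  W <- P <- matrix(0, p, 0)
  Q <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)                      # covariance direction
    nw <- sqrt(sum(w^2))
    if (nw^2 <= tol) break
    w <- w / nw
    t_score <- drop(E %*% w)
    tt <- sum(t_score^2)
    if (tt <= tol) break
    p_load <- crossprod(E, t_score) / tt
    q_load <- sum(f * t_score) / tt
    E <- E - tcrossprod(t_score, p_load)
    f <- f - t_score * q_load
    W <- cbind(W, w); P <- cbind(P, p_load); Q <- c(Q, q_load)
  }
  beta <- if (length(Q) == 0) numeric(p)
          else drop(W %*% solve(crossprod(P, W), Q))
  fit <- structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         intercept = ybar - sum(xbar * beta),
         ncomp = ncomp, ncomp_used = length(Q),
         weights = W, loadings = P, y_loadings = Q),
    class = "pls_fit")
  fit$fitted <- predict(fit, X)
  fit
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  assert_matrix(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}

#' Fit the group-mean null model
#'
#' @param y_train Non-empty numeric vector of training responses.
#' @return Object of class `null_fit` predicting `mean(y_train)` everywhere.
#' @export
fit_null <- function(y_train) {
  stopifnot(length(y_train) >= 1, !anyNA(y_train))
  structure(list(mean = mean(y_train), n_train = length(y_train)),
            class = "null_fit")
}

#' @export
predict.null_fit <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else length(newdata)
  rep(object$mean, n)
}

#' Describe a model configuration
#'
#' @param blocks Character vector of cohort block names to enter as
#'   predictors, or `NULL`/`character(0)` for the null model.
#' @param ncomp Number of PLS components (default 2; capped automatically at
#'   `min(n_train - 1, n_predictors)` when a training fold is too small).
#' @param select_ncomp If `TRUE`, choose the number of components (from
#'   `1:ncomp`) by an internal deterministic 5-fold cross-validation on the
#'   training sample, so selection stays confined to training data.
#' @param label Display label; default derived from the block names.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(blocks, ncomp = 2, select_ncomp = FALSE, label = NULL) {
  blocks <- as.character(blocks %||% character(0))
  if (is.null(label))
    label <- if (length(blocks) == 0) "null" else paste(blocks, collapse = "+")
  stopifnot(ncomp >= 1)
  structure(list(blocks = blocks, ncomp = as.integer(ncomp),
                 select_ncomp = isTRUE(select_ncomp), label = label),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s%s\n", x$label,
              if (length(x$blocks)) sprintf(" (PLS, ncomp = %d%s)", x$ncomp,
                if (x$select_ncomp) ", nested selection" else "") else " (group-mean)"))
  invisible(x)
}

# internal: deterministic inner-CV choice of ncomp on the training sample
select_ncomp_inner <- function(X, y, ncomp_max, k_inner = 5) {
  n <- nrow(X)
  k_inner <- min(k_inner, n)
  fold <- rep_len(seq_len(k_inner), n)
  cand <- seq_len(ncomp_max)
  err <- vapply(cand, function(a) {
    pred <- numeric(n)
    for (f in seq_len(k_inner)) {
      tr <- fold != f
      if (a > min(sum(tr) - 1, ncol(X))) return(Inf)
      z_test <- standardize(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])$values
      z_train <- standardize(X[tr, , drop = FALSE])$values
      pred[!tr] <- predict(fit_pls(z_train, y[tr], a), z_test)
    }
    mean((pred - y)^2)
  }, 0)
  cand[which.min(err)]
}

#' Fit a configured model on a cohort
#'
#' For a PLS spec the selected blocks are bound into one design matrix,
#' z-scored on the training cohort, and passed to [fit_pls()]; the returned
#' object carries the standardization parameters so prediction on new data is
#' one affine map. For the empty block set the group-mean null model is fit.
#'
#' @param x An `anomia_cohort` (the training sample).
#' @param spec A `model_spec`.
#' @return An object of class `fitted_model`.
#' @export
fit_model <- function(x, spec) {
  stopifnot(inherits(x, "anomia_cohort"), inherits(spec, "model_spec"))
  y <- x$response
  if (length(spec$blocks) == 0) {
    fit <- fit_null(y)
    return(structure(list(spec = spec, type = "null", fit = fit,
                          training_ids = x$patient_ids,
                          fitted = predict(fit, y)),
                     class = "fitted_model"))
  }
  X <- cohort_design(x, spec$blocks)
  ncomp_cap <- min(spec$ncomp, nrow(X) - 1, ncol(X))
  ncomp <- if (spec$select_ncomp) select_ncomp_inner(X, y, ncomp_cap)
           else ncomp_cap
  std <- standardize(X)
  fit <- fit_pls(std$values, y, ncomp)
  structure(
    list(spec = spec, type = "pls", fit = fit,
         center = std$center, scale = std$scale,
         variable_ids = colnames(X), training_ids = x$patient_ids,
         fitted = fit$fitted),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  if (x$type == "null")
    cat(sprintf("<fitted_model> null (group mean %.3f, n = %d)\n",
                x$fit$mean, length(x$training_ids)))
  else
    cat(sprintf("<fitted_model> PLS '%s': %d predictors, %d component(s), n = %d\n",
                x$spec$label, length(x$variable_ids), x$fit$ncomp_used,
                length(x$training_ids)))
  invisible(x)
}

#' Predict treatment responses from a fitted model
#'
#' @param object A `fitted_model`.
#' @param newdata Either an `anomia_cohort` (the model_spec's blocks are bound and
#'   matched) or a numeric matrix whose columns match the model's variables.
#'   Columns are matched by name; missing or extra columns raise an error
#'   naming them.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  if (object$type == "null") {
    n <- if (inherits(newdata, "anomia_cohort")) n_patients(newdata)
         else if (is.matrix(newdata)) nrow(newdata) else length(newdata)
    return(rep(object$fit$mean, n))
  }
  X <- if (inherits(newdata, "anomia_cohort"))
    cohort_design(newdata, object$spec$blocks)
  else as.matrix(newdata)
  if (is.null(colnames(X)))
    stop("`newdata` must have column names matching the model's variables",
         call. = FALSE)
  miss <- setdiff(object$variable_ids, colnames(X))
  extra <- setdiff(colnames(X), object$variable_ids)
  if (length(miss) || length(extra))
    stop(sprintf("predictor columns do not match the model: missing [%s], extra [%s]",
                 paste(miss, collapse = ", "), paste(extra, collapse = ", ")),
         call. = FALSE)
  X <- X[, object$variable_ids, drop = FALSE]
  scl <- ifelse(object$scale > 0, object$scale, 1)
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, scl, "/")
  Xs[, object$scale == 0] <- 0
  predict(object$fit, Xs)
}
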