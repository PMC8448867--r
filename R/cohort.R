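#' Assemble a modelling cohort
#'
#' A cohort bundles the per-patient predictor blocks and the treatment
#' response. Blocks are named numeric matrices sharing patient order; typical
#' blocks are `demographics` (age at onset in years, sex coded 0/1, time
#' post-stroke in months), `initial_severity` (pre-treatment trained-item
#' naming accuracy, count 0-150), `hours` (therapy hours undertaken),
#' `behavioural` (battery of assessment scores) and `lesions` (per-region
#' lesion-load fractions). The response is the change in trained-item naming
#' accuracy from pre- to post-treatment (may be negative). Missing values are
#' not permitted anywhere.
#'
#' @param patient_ids Character vector of patient ids.
#' @param blocks Named list of numeric matrices, one row per patient, with
#'   column names. Vectors of length `n` are accepted and promoted to
#'   one-column matrices named after the block.
#' @param response Numeric response vector, one value per patient.
#' @return An object of class `anomia_cohort`.
#' @export
cohort <- function(patient_ids, blocks, response) {
  n <- length(patient_ids)
  stopifnot(is.character(patient_ids), n >= 2, !anyDuplicated(patient_ids))
  if (length(response) != n || !is.numeric(response))
    stop("`response` must be numeric with one value per patient", call. = FALSE)
  if (anyNA(response)) stop("missing values in `response`", call. = FALSE)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("`blocks` must be a fully named list", call. = FALSE)
  blocks <- lapply(stats::setNames(names(blocks), names(blocks)), function(bn) {
    b <- blocks[[bn]]
    if (is.null(dim(b))) b <- matrix(b, ncol = 1, dimnames = list(NULL, bn))
    b <- as.matrix(b)
    if (nrow(b) != n)
      stop(sprintf("block '%s' has %d rows but the cohort has %d patients",
                   bn, nrow(b), n), call. = FALSE)
    if (anyNA(b))
      stop(sprintf("missing values in block '%s'", bn), call. = FALSE)
    if (is.null(colnames(b)))
      colnames(b) <- paste0(bn, "_", seq_len(ncol(b)))
    rownames(b) <- patient_ids
    b
  })
  structure(list(patient_ids = patient_ids, blocks = blocks,
                 response = as.numeric(response)),
            class = "anomia_cohort")
}

#' @export
print.anomia_cohort <- function(x, ...) {
  cat(sprintf("<anomia_cohort> %d patients; blocks: %s\n",
              length(x$patient_ids),
              paste(sprintf("%s(%d)", names(x$blocks),
                            vapply(x$blocks, ncol, 0L)), collapse = ", ")))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x An `anomia_cohort`.
#' @export
n_patients <- function(x) length(x$patient_ids)

#' Bind selected predictor blocks into one design matrix
#'
#' @param x An `anomia_cohort`.
#' @param block_names Character vector of block names, in the desired column
#'   order.
#' @return Numeric matrix with the blocks' columns side by side.
#' @export
cohort_design <- function(x, block_names) {
  stopifnot(inherits(x, "anomia_cohort"))
  missing_b <- setdiff(block_names, names(x$blocks))
  if (length(missing_b))
    stop(sprintf("cohort has no block(s): %s",
                 paste(missing_b, collapse = ", ")), call. = FALSE)
  do.call(cbind, x$blocks[block_names])
}

#' Subset a cohort by patient index
#' @param x An `anomia_cohort`.
#' @param i Integer or logical index over patients.
#' @export
subset_cohort <- function(x, i) {
  cohort(x$patient_ids[i],
         lapply(x$blocks, function(b) b[i, , drop = FALSE]),
         x$response[i])
}
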