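# Small deterministic fixtures shared across the test files.

# random 0/1 array of a given shape
random_binary_array <- function(dim, p = 0.4, seed = 1) {
  withr::with_seed(seed, array(as.integer(runif(prod(dim)) < p), dim = dim))
}

# tiny region set: `sizes[i]` voxels per region, laid out consecutively
tiny_region_set <- function(sizes, grid_dim = c(4, 4, 4), atlas_id = "toy") {
  stopifnot(sum(sizes) <= prod(grid_dim))
  offs <- cumsum(c(0, sizes[-length(sizes)]))
  region_set(
    lapply(seq_along(sizes), function(i)
      list(region_id = sprintf("r%d", i), atlas_id = atlas_id,
           voxels = offs[i] + seq_len(sizes[i]))),
    grid_dim = grid_dim)
}

# small random modelling cohort with independent predictor blocks
toy_cohort <- function(n = 20, p_lesions = 5, seed = 1, beta = NULL,
                       noise_sd = 0.1) {
  withr::with_seed(seed, {
    L <- matrix(runif(n * p_lesions), n,
                dimnames = list(NULL, sprintf("R%02d", seq_len(p_lesions))))
    hrs <- rnorm(n, 73, 25)
    if (is.null(beta)) beta <- rnorm(p_lesions)
    y <- drop(L %*% beta) + 0.2 * hrs + rnorm(n, 0, noise_sd)
    cohort(sprintf("P%02d", seq_len(n)),
           blocks = list(lesions = L, hours = hrs),
           response = y)
  })
}

# a hand-built purely linear fitted model (identity standardization), so
# interpretation tests control the coefficient vector exactly
fake_linear_model <- function(beta, intercept = 0) {
  p <- length(beta)
  stopifnot(!is.null(names(beta)))
  fit <- structure(
    list(coefficients = beta, intercept = intercept, ncomp = 1,
         ncomp_used = 1, weights = NULL, loadings = NULL, y_loadings = NULL),
    class = "pls_fit")
  structure(
    list(spec = model_spec("custom", label = "fake"), type = "pls",
         fit = fit, center = stats::setNames(rep(0, p), names(beta)),
         scale = stats::setNames(rep(1, p), names(beta)),
         variable_ids = names(beta), training_ids = character(0)),
    class = "fitted_model")
}

# counting-based signed-rank oracle, independent of the package's ranking
oracle_signed_rank <- function(a, b) {
  d <- (a - b)[a != b]
  if (length(d) == 0) return(0)
  W <- 0
  for (i in seq_along(d)) {
    if (d[i] <= 0) next
    smaller <- sum(abs(d) < abs(d[i]))
    equal <- sum(abs(d) == abs(d[i]))
    W <- W + smaller + (equal + 1) / 2
  }
  W
}
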