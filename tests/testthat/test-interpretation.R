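test_that("an ignored variable gets a null influence weight", {
  withr::with_seed(70, X <- matrix(rnorm(18 * 3), 18,
                                   dimnames = list(NULL, c("a", "b", "v"))))
  m <- fake_linear_model(c(a = 2, b = -1, v = 0))
  w <- perturb_and_weigh(m, X, 1000, seed = 71)
  expect_lt(abs(w$weights[["v"]]), 0.02)
  expect_true(all(abs(w$weights) <= 1))
})

test_that("a single positive-coefficient predictor has weight exactly one", {
  withr::with_seed(72, X <- matrix(rnorm(18), 18, dimnames = list(NULL, "x")))
  m <- fake_linear_model(c(x = 1.7), intercept = 3)
  w <- perturb_and_weigh(m, X, 50, seed = 73)
  expect_equal(unname(w$weights), 1)   # prediction is monotone affine in x
})

test_that("planted coefficient signs are recovered on independent predictors", {
  beta <- c(x1 = 3, x2 = -2, x3 = 1.5, x4 = -1, x5 = 2.5,
            x6 = -3, x7 = 1, x8 = -1.5, x9 = 2, x10 = -2.5)
  withr::with_seed(74, X <- matrix(rnorm(18 * 10), 18,
                                   dimnames = list(NULL, names(beta))))
  m <- fake_linear_model(beta)
  w <- perturb_and_weigh(m, X, 1000, seed = 75)
  expect_equal(sign(w$weights), sign(beta))
})

test_that("perturbation weights are deterministic given the seed", {
  coh <- toy_cohort(seed = 76)
  m <- fit_model(coh, model_spec(c("lesions", "hours")))
  X <- cohort_design(coh, c("lesions", "hours"))
  w1 <- perturb_and_weigh(m, X, 200, seed = 77)
  w2 <- perturb_and_weigh(m, X, 200, seed = 77)
  expect_identical(w1$weights, w2$weights)
  expect_equal(cor(w1$weights, w2$weights), 1)
})

test_that("weight stability improves with the iteration count", {
  coh <- toy_cohort(seed = 78)
  m <- fit_model(coh, model_spec(c("lesions", "hours")))
  X <- cohort_design(coh, c("lesions", "hours"))
  st10 <- stability_check(m, X, n_runs = 6, n_iterations = 10, seed = 79)
  st1000 <- stability_check(m, X, n_runs = 6, n_iterations = 1000, seed = 79)
  expect_lt(as.numeric(st10), as.numeric(st1000))
  expect_gt(as.numeric(st1000), 0.99)
  C <- attr(st1000, "correlations")
  expect_equal(dim(C), c(6, 6))
  expect_true(all(C[upper.tri(C)] >= as.numeric(st1000)))
})

test_that("weights converge to the closed-form correlation on three variables", {
  # linear model, correlated predictors; enumerate the 8 inclusion states
  n <- 120
  withr::with_seed(80, {
    z <- rnorm(n)
    X <- cbind(a = z + rnorm(n, 0, 0.6), b = -0.8 * z + rnorm(n, 0, 0.6),
               c = rnorm(n))
  })
  beta <- c(a = 1.5, b = 1, c = -0.5)
  m <- fake_linear_model(beta)
  S <- cov(X) * (n - 1) / n
  states <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        c = c(TRUE, FALSE))
  oracle <- vapply(colnames(X), function(v) {
    covs <- vars <- numeric(nrow(states))
    for (i in seq_len(nrow(states))) {
      sh <- unlist(states[i, ])            # TRUE = shuffled
      covs[i] <- if (sh[v]) beta[v] * S[v, v]
                 else sum(beta[!sh] * S[v, !sh])
      Sm <- S
      Sm[sh, ] <- 0; Sm[, sh] <- 0
      diag(Sm) <- diag(S)
      vars[i] <- drop(beta %*% Sm %*% beta)
    }
    mean(covs) / sqrt(S[v, v] * mean(vars))
  }, 0)
  w <- perturb_and_weigh(m, X, 4000, seed = 81)
  expect_equal(unname(w$weights), unname(oracle), tolerance = 0.05)
})

test_that("proxy-region correlations match brute-force column-wise Pearson", {
  # two-block anticorrelated lesion structure
  withr::with_seed(82, {
    g <- rnorm(12)
    A <- sapply(1:3, function(i) pmin(pmax(0.5 + 0.3 * g + rnorm(12, 0, 0.1), 0), 1))
    B <- sapply(1:3, function(i) pmin(pmax(0.5 - 0.3 * g + rnorm(12, 0, 0.1), 0), 1))
  })
  M <- cbind(A, B)
  colnames(M) <- sprintf("R%02d", 1:6)
  pr <- proxy_region_analysis(M, "R01")
  expect_length(pr$correlations, 5)                  # target excluded
  expect_false("R01" %in% names(pr$correlations))
  for (rr in names(pr$correlations))
    expect_equal(pr$correlations[[rr]], cor(M[, "R01"], M[, rr]))
  expect_true(all(pr$correlations[c("R04", "R05", "R06")] < 0))
  Mz <- M; Mz[, 2] <- 0.5
  expect_error(proxy_region_analysis(Mz, "R02"), "zero load variance")
  expect_error(proxy_region_analysis(M, "nope"), "not present")
})

test_that("weight reports rank variables and annotate regions", {
  empty <- structure(list(variable_ids = character(0),
                          weights = setNames(numeric(0), character(0)),
                          n_iterations = 1L, inclusion_p = 0.5,
                          perturb = "shuffle", cor_method = "pearson",
                          seed = 1L),
                     class = "influence_weights")
  expect_equal(nrow(weight_report(empty)), 0)
  w <- empty
  w$variable_ids <- c("a", "b")
  w$weights <- c(a = 0.5, b = -0.7)
  expect_equal(weight_report(w)$variable_id, c("a", "b"))           # signed
  expect_equal(weight_report(w, by = "abs")$variable_id, c("b", "a"))
  man <- data.frame(region_id = c("a", "b"), atlas_id = c("t1", "t1"),
                    n_voxels = c(10L, 20L))
  rep2 <- weight_report(w, man)
  expect_equal(rep2$atlas_id, c("t1", "t1"))
  coh <- toy_cohort(seed = 83)
  m <- fit_model(coh, model_spec(c("lesions", "hours")))
  ww <- perturb_and_weigh(m, cohort_design(coh, c("lesions", "hours")),
                          100, seed = 84)
  expect_equal(nrow(weight_report(ww)), 6)   # one row per model variable
})
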