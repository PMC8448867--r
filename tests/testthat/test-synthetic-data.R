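test_that("the toy atlas tiles the grid and degenerates gracefully", {
  cfg <- synthetic_config(grid = c(6, 6, 4), n_regions = 9, seed = 5)
  atlas <- make_toy_atlas(cfg)
  sizes <- vapply(atlas$regions, function(r) length(r$voxels), 0L)
  expect_equal(sum(sizes), 6 * 6 * 4)          # partition covers the grid
  expect_true(all(sizes >= 1))
  expect_equal(anyDuplicated(unlist(lapply(atlas$regions, `[[`, "voxels"))), 0)
  # one voxel per region at the degenerate limit
  cfg1 <- synthetic_config(grid = c(3, 3, 2), n_regions = 18, seed = 6)
  a1 <- make_toy_atlas(cfg1)
  expect_true(all(vapply(a1$regions, function(r) length(r$voxels), 0L) == 1))
  # determinism
  expect_identical(make_toy_atlas(cfg)$regions, make_toy_atlas(cfg)$regions)
})

test_that("the optional second atlas adds overlapping duplicate regions", {
  cfg <- synthetic_config(n_regions = 10, overlap_atlas = TRUE, seed = 7)
  atlas <- make_toy_atlas(cfg)
  man <- region_manifest(atlas)
  expect_equal(sum(man$atlas_id == "toy2"), 5)
  base_vox <- unlist(lapply(atlas$regions[man$atlas_id == "toy1"], `[[`, "voxels"))
  dup_vox <- unlist(lapply(atlas$regions[man$atlas_id == "toy2"], `[[`, "voxels"))
  expect_true(any(dup_vox %in% base_vox))      # genuine overlap retained
  masks <- make_lesions(cfg, atlas)
  enc <- encode_cohort(masks, atlas, drop_zero_variance = FALSE)
  expect_equal(ncol(enc$values), 15)           # overlap kept as extra columns
})

test_that("lesions are confined to the territory and zero-size blobs vanish", {
  cfg0 <- synthetic_config(blob_size = 0, seed = 8)
  masks0 <- make_lesions(cfg0, make_toy_atlas(cfg0))
  expect_true(all(vapply(masks0, function(m) sum(m$voxel_grid), 0) == 0))
  cfg <- synthetic_config(seed = 9)
  atlas <- make_toy_atlas(cfg)
  masks <- make_lesions(cfg, atlas)
  x_max <- ceiling(cfg$grid[1] * cfg$territory_frac)
  for (m in masks) {
    hit <- which(m$voxel_grid == 1, arr.ind = TRUE)
    expect_true(all(hit[, 1] <= x_max))
    expect_gt(nrow(hit), 0)
  }
  # regions wholly outside the territory are pruned by the encoder
  enc <- encode_cohort(masks, atlas)
  outside <- vapply(atlas$regions, function(r)
    all(arrayInd(r$voxels, cfg$grid)[, 1] > x_max), NA)
  expect_true(all(region_ids(atlas)[outside] %in% enc$dropped_region_ids))
  expect_gt(length(enc$dropped_region_ids), 0)
})

test_that("adjacent regions have more correlated loads than distant regions", {
  cfg <- synthetic_config(seed = 10)
  atlas <- make_toy_atlas(cfg)
  enc <- encode_cohort(make_lesions(cfg, atlas), atlas)
  keep <- match(enc$region_ids, region_ids(atlas))
  cents <- t(vapply(atlas$regions[keep], function(r)
    colMeans(arrayInd(r$voxels, cfg$grid)), numeric(3)))
  D <- as.matrix(dist(cents))
  ok <- apply(enc$values, 2, sd) > 0
  C <- suppressWarnings(cor(enc$values))
  ut <- upper.tri(D)
  pairs_ok <- ut & outer(ok, ok, "&")
  adj <- D < quantile(D[pairs_ok], 0.25)
  far <- D > quantile(D[pairs_ok], 0.75)
  expect_gt(mean(C[pairs_ok & adj]), mean(C[pairs_ok & far]))
})

test_that("therapy hours follow the configured dose distribution", {
  means <- vapply(1:5, function(s) {
    sc <- simulate_cohort(synthetic_config(seed = s))
    mean(sc$cohort$blocks$hours)
  }, 0)
  tol <- 3 * 25 / sqrt(18)
  expect_true(all(abs(means - 73) < tol))
  expect_true(all(vapply(1:3, function(s)
    min(simulate_cohort(synthetic_config(seed = s))$cohort$blocks$hours), 0) >= 1))
})

test_that("responses decompose into planted signal plus recoverable noise", {
  sc <- simulate_cohort(synthetic_config(seed = 11))
  expect_equal(sc$cohort$response - sc$truth$noiseless, sc$truth$noise)
  expect_equal(sd(sc$truth$noise) / sd(sc$truth$noiseless), 0.1,
               tolerance = 0.6)  # one draw of n = 18 around the 10% target
  # noiseless configuration is exactly linear and exactly fit at full rank
  sc0 <- simulate_cohort(synthetic_config(n_regions = 10, noise_sd = 0,
                                          seed = 12))
  m <- fit_model(sc0$cohort, model_spec(c("lesions", "hours"), ncomp = 17))
  expect_lt(max(abs(m$fitted - sc0$cohort$response)), 1e-8)
  # the planted map touches only the configured number of regions
  expect_equal(sum(sc$truth$weights != 0), 6)
  expect_true(all(sc$truth$weights <= 0))
})

test_that("the generator is reproducible from its config and seed", {
  a <- simulate_cohort(synthetic_config(seed = 13))
  b <- simulate_cohort(synthetic_config(seed = 13))
  expect_identical(a$cohort$response, b$cohort$response)
  expect_identical(a$loads$values, b$loads$values)
  expect_identical(a$cohort$blocks$behavioural, b$cohort$blocks$behavioural)
  c_ <- simulate_cohort(synthetic_config(seed = 14))
  expect_false(identical(a$cohort$response, c_$cohort$response))
})

test_that("under a global null no model is declared better than the null model", {
  # n = 48: large enough that a chance alignment of the collinear lesion
  # loads with the noise cannot dominate a whole dataset realization (at
  # n = 18 such alignments are common and every fold learns them — a
  # dataset-level hazard of CV model comparison discussed in the vignette)
  wins <- vapply(1:15, function(s) {
    cfg <- synthetic_config(n_patients = 48, seed = 100 + s,
                            weight_scale = 0, beta_hours = 0,
                            noise_sd = 10)
    sc <- simulate_cohort(cfg)
    plan <- make_fold_plan(48, 10, 30, seed = 200 + s)
    null_cv <- cross_validate(sc$cohort, model_spec(NULL), plan)
    any(vapply(list("hours", "lesions", c("lesions", "hours")), function(bl) {
      cv <- cross_validate(sc$cohort, model_spec(bl), plan)
      ct <- paired_permutation_test(cv$mse, null_cv$mse, 999, seed = 300 + s)
      min(1, ct$p_value * 15) < 0.05 && median(cv$mse) < median(null_cv$mse)
    }, NA))
  }, NA)
  expect_gte(mean(!wins), 0.9)
})
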