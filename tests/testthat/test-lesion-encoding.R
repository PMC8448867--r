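test_that("probabilistic regions binarize with an inclusive 50% boundary", {
  z <- array(0, c(2, 2, 2))
  expect_equal(binarize_region(z), array(0L, c(2, 2, 2)))
  m <- array(c(0.49, 0.50, 0.51, rep(0, 5)), c(2, 2, 2))
  out <- binarize_region(m, 0.5)
  expect_equal(as.vector(out)[1:3], c(0L, 1L, 1L))
  expect_error(binarize_region(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(binarize_region(array(-0.1, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("binarization matches voxel-wise brute force on a random map", {
  pm <- withr::with_seed(3, array(runif(125), c(5, 5, 5)))
  out <- binarize_region(pm, 0.5)
  brute <- array(0L, dim(pm))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    brute[i, j, k] <- as.integer(pm[i, j, k] >= 0.5)
  expect_identical(out, brute)
})

test_that("lesion load is the covered fraction of the region", {
  grid <- array(0L, c(4, 4, 4))
  grid[1:10] <- 1L
  expect_equal(lesion_load(grid, 1:10), 1.0)          # full overlap
  expect_equal(lesion_load(array(0L, c(4, 4, 4)), 1:10), 0.0)  # empty lesion
  expect_error(lesion_load(grid, integer(0)), "empty")
  reg <- array(0L, c(4, 4, 4)); reg[c(3, 9, 17)] <- 1L
  expect_error(lesion_load(array(0L, c(3, 3, 3)), reg), "shapes")
})

test_that("lesion load matches a brute-force voxel loop on random fixtures", {
  for (s in 1:5) {
    mask <- random_binary_array(c(4, 4, 4), 0.5, seed = s)
    region_vox <- withr::with_seed(100 + s, sample.int(64, 8))
    got <- lesion_load(mask, region_vox)
    hits <- 0
    for (v in region_vox) hits <- hits + (mask[v] == 1)
    expect_equal(got, hits / 8)
    # integer recovery: load times region size is exactly the voxel count
    expect_equal(got * 8, round(got * 8))
  }
})

test_that("load is monotone under adding lesioned voxels", {
  region_vox <- 1:16
  mask <- array(0L, c(4, 4, 4))
  prev <- 0
  for (v in c(2, 5, 11, 16, 40)) {
    mask[v] <- 1L
    cur <- lesion_load(mask, region_vox)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("encoding prunes exactly-all-zero regions and records them", {
  rs <- tiny_region_set(c(4, 4, 4, 4, 4))
  masks <- lapply(1:3, function(i) {
    g <- array(0L, c(4, 4, 4))
    g[(i - 1) * 4 + 1:4] <- 1L      # patient i hits region i
    if (i == 1) g[13:14] <- 1L      # patient 1 also clips region 4
    lesion_mask(sprintf("P%d", i), g, space_tag = rs$space_tag)
  })
  enc <- encode_cohort(masks, rs)   # region 5 untouched by every lesion
  expect_equal(ncol(enc$values), 4)
  expect_equal(enc$dropped_region_ids, "r5")
  expect_equal(enc$region_ids, c("r1", "r2", "r3", "r4"))
  expect_true(all(enc$values >= 0 & enc$values <= 1))
  expect_equal(enc$values["P1", "r4"], 2 / 4)
})

test_that("encoding with no all-zero region is a no-op prune", {
  rs <- tiny_region_set(c(8, 8))
  masks <- lapply(1:3, function(i)
    lesion_mask(sprintf("P%d", i), random_binary_array(c(4, 4, 4), 0.9, i),
                space_tag = rs$space_tag))
  enc <- encode_cohort(masks, rs)
  expect_length(enc$dropped_region_ids, 0)
  expect_equal(ncol(enc$values), 2)
})

test_that("cohort encoding equals stacked per-patient lesion_load calls", {
  cfg <- synthetic_config(n_patients = 6, grid = c(10, 10, 10),
                          n_regions = 8, blob_size = 60, seed = 4)
  atlas <- make_toy_atlas(cfg)
  masks <- make_lesions(cfg, atlas)
  enc <- encode_cohort(masks, atlas, drop_zero_variance = FALSE)
  for (i in seq_along(masks)) {
    for (j in seq_along(atlas$regions)) {
      expect_equal(enc$values[i, j],
                   lesion_load(masks[[i]], atlas$regions[[j]]$voxels))
    }
  }
})

test_that("encoding is permutation-equivariant over patients", {
  rs <- tiny_region_set(c(6, 6, 6))
  masks <- lapply(1:4, function(i)
    lesion_mask(sprintf("P%d", i), random_binary_array(c(4, 4, 4), 0.4, i),
                space_tag = rs$space_tag))
  perm <- c(3, 1, 4, 2)
  a <- encode_cohort(masks, rs, drop_zero_variance = FALSE)
  b <- encode_cohort(masks[perm], rs, drop_zero_variance = FALSE)
  expect_equal(unname(b$values), unname(a$values[perm, ]))
  expect_equal(b$patient_ids, a$patient_ids[perm])
})

test_that("mixed template spaces fail naming the offending patient", {
  rs <- tiny_region_set(c(8, 8))
  good <- lesion_mask("P1", array(0L, c(4, 4, 4)), space_tag = rs$space_tag)
  bad <- lesion_mask("P2", array(0L, c(4, 4, 4)), space_tag = "other-grid")
  expect_error(encode_cohort(list(good, bad), rs), "P2")
})

test_that("NIfTI masks and probabilistic atlas images round-trip", {
  td <- withr::local_tempdir()
  gd <- c(6, 6, 6)
  m1 <- random_binary_array(gd, 0.3, seed = 11)
  m2 <- random_binary_array(gd, 0.3, seed = 12)
  RNifti::writeNifti(RNifti::asNifti(m1), file.path(td, "p1.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(m2), file.path(td, "p2.nii.gz"))
  prob <- withr::with_seed(13, array(runif(prod(gd)), gd))
  hard <- array(as.numeric(random_binary_array(gd, 0.5, 14)), gd)
  RNifti::writeNifti(RNifti::asNifti(prob), file.path(td, "regA.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(hard), file.path(td, "regB.nii.gz"))
  write.table(
    data.frame(region_id = c("A", "B"), atlas_id = c("at1", "at2"),
               file = c("regA.nii.gz", "regB.nii.gz")),
    file.path(td, "manifest.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  masks <- read_lesion_masks(file.path(td, c("p1.nii.gz", "p2.nii.gz")))
  expect_equal(masks[[1]]$patient_id, "p1")
  expect_equal(masks[[1]]$voxel_grid, m1)
  rs <- read_region_set(file.path(td, "manifest.tsv"))
  expect_equal(region_ids(rs), c("A", "B"))
  expect_equal(rs$regions[[1]]$voxels, which(prob >= 0.5))  # binarized
  expect_equal(rs$regions[[2]]$voxels, which(hard != 0))    # already binary
  enc <- encode_cohort(masks, rs, drop_zero_variance = FALSE)
  out_csv <- file.path(td, "loads.csv")
  write_load_matrix(enc, out_csv)
  back <- read.csv(out_csv, check.names = FALSE)
  expect_equal(back$patient_id, c("p1", "p2"))
  expect_equal(as.matrix(back[, -1]), enc$values, ignore_attr = TRUE)
  man_tsv <- file.path(td, "regions.tsv")
  write_region_manifest(rs, man_tsv)
  man <- read.delim(man_tsv)
  expect_equal(man$n_voxels,
               unname(vapply(rs$regions, function(r) length(r$voxels), 0L)))
})
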