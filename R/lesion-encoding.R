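#' Lesion masks, region sets and lesion-load encoding
#'
#' A patient's lesion is represented as a binary voxel grid in a common
#' template space; anatomical regions of interest are voxel sets on the same
#' grid, possibly drawn from several atlases and possibly overlapping.
#' Lesion "load" in a region is the fraction of that region's voxels that
#' the lesion covers, which collapses a whole-brain mask into a short vector
#' of interpretable per-region damage fractions.
#'
#' @name lesion-encoding
NULL

#' Construct a lesion mask
#'
#' @param patient_id Single string identifying the patient.
#' @param voxel_grid 3-D array whose values are exactly 0 or 1
#'   (1 = lesioned voxel).
#' @param voxel_volume Volume of one voxel in mm^3 (default 8, i.e. 2 mm
#'   isotropic).
#' @param space_tag String identifying the template space / grid. Masks and
#'   region sets may only be combined when their tags match.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(patient_id, voxel_grid, voxel_volume = 8,
                        space_tag = paste(dim(voxel_grid), collapse = "x")) {
  stopifnot(is.character(patient_id), length(patient_id) == 1)
  if (length(dim(voxel_grid)) != 3)
    stop("`voxel_grid` must be a 3-D array", call. = FALSE)
  v <- as.vector(voxel_grid)
  if (anyNA(v) || !all(v == 0 | v == 1))
    stop(sprintf("lesion mask for patient '%s' must contain only 0/1 values",
                 patient_id), call. = FALSE)
  structure(
    list(patient_id = patient_id,
         voxel_grid = array(as.integer(voxel_grid), dim = dim(voxel_grid)),
         voxel_volume = voxel_volume,
         space_tag = space_tag),
    class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> patient %s: %d lesioned voxels (%.1f ml) on %s grid\n",
              x$patient_id, sum(x$voxel_grid),
              sum(x$voxel_grid) * x$voxel_volume / 1000,
              paste(dim(x$voxel_grid), collapse = "x")))
  invisible(x)
}

#' Construct a region set
#'
#' Regions are stored as voxel index vectors into a shared grid. Regions may
#' overlap (e.g. the same structure represented in two atlases); every region
#' must contain at least one voxel. Column order downstream is the order of
#' regions here, which callers should keep grouped by atlas.
#'
#' @param regions A list; each element a list with fields `region_id`,
#'   `atlas_id`, and `voxels` (either a 3-D 0/1 array on the shared grid or an
#'   integer vector of voxel indices).
#' @param grid_dim Integer vector of length 3, the shared grid shape.
#' @param space_tag Template-space tag (see [lesion_mask()]).
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions, grid_dim,
                       space_tag = paste(grid_dim, collapse = "x")) {
  stopifnot(length(grid_dim) == 3, length(regions) >= 1)
  n_vox <- prod(grid_dim)
  parsed <- lapply(regions, function(r) {
    stopifnot(!is.null(r$region_id), !is.null(r$atlas_id), !is.null(r$voxels))
    vox <- r$voxels
    if (is.array(vox)) {
      if (!identical(dim(vox), as.integer(grid_dim)))
        stop(sprintf("region '%s' grid shape does not match the region set",
                     r$region_id), call. = FALSE)
      vox <- which(vox != 0)
    }
    vox <- as.integer(vox)
    if (length(vox) < 1 || any(vox < 1 | vox > n_vox))
      stop(sprintf("region '%s' must have >= 1 member voxel inside the grid",
                   r$region_id), call. = FALSE)
    list(region_id = as.character(r$region_id),
         atlas_id = as.character(r$atlas_id), voxels = vox)
  })
  ids <- vapply(parsed, `[[`, "", "region_id")
  if (anyDuplicated(ids))
    stop("region_id values must be unique across atlases", call. = FALSE)
  structure(
    list(regions = parsed, grid_dim = as.integer(grid_dim),
         space_tag = space_tag),
    class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions from %d atlas(es) on %s grid\n",
              length(x$regions),
              length(unique(vapply(x$regions, `[[`, "", "atlas_id"))),
              paste(x$grid_dim, collapse = "x")))
  invisible(x)
}

#' Region ids of a region set
#' @param regions A `region_set`.
#' @return Character vector of region ids, in column order.
#' @export
region_ids <- function(regions) {
  unname(vapply(regions$regions, `[[`, "", "region_id"))
}

#' Region manifest table
#'
#' @param regions A `region_set`.
#' @return A data frame with columns `region_id`, `atlas_id`, `n_voxels`.
#' @export
region_manifest <- function(regions) {
  data.frame(
    region_id = region_ids(regions),
    atlas_id = unname(vapply(regions$regions, `[[`, "", "atlas_id")),
    n_voxels = unname(vapply(regions$regions, function(r) length(r$voxels), 0L)),
    stringsAsFactors = FALSE)
}

#' Binarize a probabilistic region image
#'
#' Probabilistic atlas regions are re-encoded as binary membership images at
#' a 50% threshold by default. The boundary is inclusive: a voxel with
#' probability exactly equal to the threshold is a member.
#'
#' @param prob_map 3-D array of membership probabilities in \[0, 1\].
#' @param threshold Membership threshold (default 0.5).
#' @return A 3-D integer 0/1 array of the same shape.
#' @export
binarize_region <- function(prob_map, threshold = 0.5) {
  if (anyNA(prob_map) || any(prob_map < 0) || any(prob_map > 1))
    stop("probabilistic region values must lie in [0, 1]", call. = FALSE)
  assert_scalar_number(threshold)
  out <- array(as.integer(prob_map >= threshold), dim = dim(prob_map))
  out
}

#' Lesion load of a mask in one region
#'
#' The fraction of the region's voxels that are lesioned:
#' `|mask & region| / |region|`, always in \[0, 1\].
#'
#' @param mask A `lesion_mask` or a 3-D 0/1 array.
#' @param region A 3-D 0/1 membership array on the same grid, or an integer
#'   vector of voxel indices.
#' @param grid_dim Required when `region` is an index vector and `mask` is a
#'   bare array; otherwise inferred.
#' @return A single number in \[0, 1\].
#' @export
lesion_load <- function(mask, region, grid_dim = NULL) {
  grid <- if (inherits(mask, "lesion_mask")) mask$voxel_grid else mask
  if (length(dim(grid)) != 3)
    stop("`mask` must be (or contain) a 3-D array", call. = FALSE)
  if (is.array(region)) {
    if (!identical(dim(region), dim(grid)))
      stop("mask and region grid shapes differ", call. = FALSE)
    region <- which(region != 0)
  }
  if (length(region) == 0)
    stop("region is empty: lesion load is undefined for empty regions",
         call. = FALSE)
  sum(grid[region]) / length(region)
}

#' Encode a cohort of lesion masks as a lesion-load matrix
#'
#' Builds the patients x regions matrix of lesion-load fractions. With
#' `drop_zero_variance = TRUE` (the default, mirroring standard practice when
#' all lesions sit in one hemisphere and many regions are never damaged),
#' columns whose entries are all exactly zero are removed and recorded, so
#' models never see structurally uninformative predictors.
#'
#' @param masks List of `lesion_mask` objects.
#' @param regions A `region_set` in the same template space.
#' @param drop_zero_variance Drop all-zero columns? Default `TRUE`. Only
#'   exactly-all-zero columns are dropped, never merely low-variance ones.
#' @return An object of class `lesion_load_matrix` with fields `values`
#'   (patients x regions matrix), `patient_ids`, `region_ids`,
#'   `dropped_region_ids`, `region_sizes` and `space_tag`.
#' @export
encode_cohort <- function(masks, regions, drop_zero_variance = TRUE) {
  stopifnot(inherits(regions, "region_set"), length(masks) >= 1)
  for (m in masks) {
    if (!inherits(m, "lesion_mask"))
      stop("`masks` must be a list of lesion_mask objects", call. = FALSE)
    if (!identical(m$space_tag, regions$space_tag))
      stop(sprintf(
        "patient '%s' mask is in space '%s' but the region set is in '%s'",
        m$patient_id, m$space_tag, regions$space_tag), call. = FALSE)
    if (!identical(dim(m$voxel_grid), regions$grid_dim))
      stop(sprintf("patient '%s' mask grid shape does not match the region set",
                   m$patient_id), call. = FALSE)
  }
  ids <- vapply(masks, `[[`, "", "patient_id")
  rids <- region_ids(regions)
  sizes <- vapply(regions$regions, function(r) length(r$voxels), 0L)
  vals <- vapply(regions$regions, function(r) {
    vapply(masks, function(m) sum(m$voxel_grid[r$voxels]), 0) / length(r$voxels)
  }, numeric(length(masks)))
  vals <- matrix(vals, nrow = length(masks), ncol = length(rids),
                 dimnames = list(ids, rids))
  dropped <- character(0)
  if (isTRUE(drop_zero_variance)) {
    all_zero <- colSums(vals != 0) == 0
    dropped <- rids[all_zero]
    vals <- vals[, !all_zero, drop = FALSE]
    rids <- rids[!all_zero]
    sizes <- sizes[!all_zero]
  }
  structure(
    list(values = vals, patient_ids = ids, region_ids = rids,
         dropped_region_ids = dropped,
         region_sizes = stats::setNames(sizes, rids),
         space_tag = regions$space_tag),
    class = "lesion_load_matrix")
}

#' @export
print.lesion_load_matrix <- function(x, ...) {
  cat(sprintf("<lesion_load_matrix> %d patients x %d regions (%d all-zero regions dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped_region_ids)))
  invisible(x)
}

# NIfTI and tabular IO ------------------------------------------------------

#' Read lesion masks from NIfTI files
#'
#' @param paths Character vector of NIfTI file paths, one per patient.
#' @param patient_ids Patient ids; default the file base names.
#' @param space_tag Template-space tag shared by the files; default derived
#'   from the first image's grid shape.
#' @return List of `lesion_mask` objects.
#' @export
read_lesion_masks <- function(paths, patient_ids = NULL, space_tag = NULL) {
  if (is.null(patient_ids))
    patient_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  imgs <- lapply(paths, function(p) {
    a <- as.array(RNifti::readNifti(p))
    array(as.integer(a != 0), dim = dim(a))
  })
  if (is.null(space_tag))
    space_tag <- paste(dim(imgs[[1]]), collapse = "x")
  Map(function(id, g) lesion_mask(id, g, space_tag = space_tag),
      patient_ids, imgs)
}

#' Read a region set from a manifest of NIfTI region images
#'
#' The manifest is a TSV with columns `region_id`, `atlas_id`, `file`
#' (NIfTI path, relative to `dir`). Images containing values strictly
#' between 0 and 1 are treated as probabilistic and binarized with
#' [binarize_region()] at `threshold`.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param dir Directory against which `file` entries are resolved; default
#'   the manifest's directory.
#' @param threshold Binarization threshold for probabilistic images.
#' @param space_tag Template-space tag; default derived from the grid.
#' @return A `region_set`.
#' @export
read_region_set <- function(manifest_path, dir = dirname(manifest_path),
                            threshold = 0.5, space_tag = NULL) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "atlas_id", "file") %in% names(man)))
  imgs <- lapply(file.path(dir, man$file), function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (any(a > 0 & a < 1)) binarize_region(a, threshold)
    else array(as.integer(a != 0), dim = dim(a))
  })
  gd <- dim(imgs[[1]])
  if (is.null(space_tag)) space_tag <- paste(gd, collapse = "x")
  region_set(
    Map(function(id, at, img) list(region_id = id, atlas_id = at, voxels = img),
        man$region_id, man$atlas_id, imgs),
    grid_dim = gd, space_tag = space_tag)
}

#' Write a lesion-load matrix as CSV
#'
#' First column `patient_id`, one further column per retained region.
#'
#' @param loads A `lesion_load_matrix`.
#' @param path Output CSV path.
#' @export
write_load_matrix <- function(loads, path) {
  df <- data.frame(patient_id = loads$patient_ids, loads$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a region manifest as TSV
#' @param regions A `region_set`.
#' @param path Output TSV path.
#' @export
write_region_manifest <- function(regions, path) {
  utils::write.table(region_manifest(regions), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
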