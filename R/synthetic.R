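#' Synthetic lesion cohorts with planted structure
#'
#' The generator emulates the statistical structure the analysis assumes,
#' so every stage can be exercised without patient data: contiguous lesion
#' "blobs" grown by voxel random walks inside a restricted territory (the
#' analogue of a single-hemisphere lesion distribution), which yields
#' strongly correlated loads between neighbouring regions and a set of
#' never-lesioned regions that the encoder prunes; lesion foci drawn from
#' two sub-territories, so loads in one block anticorrelate with loads in
#' the other and a spared region can act as a statistical proxy for damage
#' elsewhere; therapy hours around 73 +/- 25; and responses built from a
#' planted region-weight map plus an hours term (optionally an
#' hours-by-lesion interaction) plus Gaussian noise whose sd defaults to 10%
#' of the noiseless signal's sd.
#'
#' @name synthetic-data
NULL

#' Generator configuration
#'
#' @param n_patients Cohort size (default 18).
#' @param grid Toy template grid shape (default 20 x 20 x 20 voxels).
#' @param n_regions Number of atlas regions tiling the grid (default 40).
#' @param territory_frac Fraction of the grid's first axis that lesions may
#'   occupy (default 0.5): regions wholly outside this territory are never
#'   damaged and exercise the zero-load pruning rule.
#' @param n_blobs Lesion blobs per patient (default 3).
#' @param blob_size Mean blob size in voxels (default 180); per-blob sizes
#'   are log-normally dispersed around it so lesion volumes vary realistically.
#' @param lesion_shape `"walk"` (default; contiguous voxel random walk) or
#'   `"sphere"` (solid spheres of matched volume).
#' @param n_negative_regions Number of regions (nearest the first lesion
#'   focus) given negative planted weights (default 6).
#' @param weight_scale Planted weight for those regions, in response units
#'   per unit load (default -25: full damage in one such region costs 25
#'   naming-count points).
#' @param beta_hours Planted therapy-hours coefficient (default 0.25
#'   response units per hour).
#' @param beta_interaction Planted hours-by-lesion interaction coefficient
#'   (default 0, i.e. a purely additive ground truth).
#' @param hours_mean,hours_sd Therapy-hours distribution (default 73 and 25
#'   hours; draws are truncated below at 1 hour).
#' @param noise_frac Response noise sd as a fraction of the noiseless
#'   signal's sd (default 0.1); ignored when `noise_sd` is given.
#' @param noise_sd Absolute response noise sd (default `NULL`).
#' @param n_behavioural Number of behavioural scores (default 28), generated
#'   as noisy linear mixtures of the lesion loads to emulate the
#'   behaviour-lesion collinearity seen in real batteries.
#' @param response_intercept Baseline response level (default 40 counts).
#' @param round_response Round responses to integers? Default `FALSE`.
#' @param overlap_atlas Add a second atlas of overlapping duplicate regions
#'   (default `FALSE`), to exercise multi-atlas overlap retention.
#' @param seed Master seed for the whole generator.
#' @return A `generator_config` list.
#' @export
synthetic_config <- function(n_patients = 18, grid = c(20, 20, 20),
                             n_regions = 40, territory_frac = 0.5,
                             n_blobs = 3, blob_size = 180,
                             lesion_shape = c("walk", "sphere"),
                             n_negative_regions = 6, weight_scale = -25,
                             beta_hours = 0.25, beta_interaction = 0,
                             hours_mean = 73, hours_sd = 25,
                             noise_frac = 0.1, noise_sd = NULL,
                             n_behavioural = 28, response_intercept = 40,
                             round_response = FALSE, overlap_atlas = FALSE,
                             seed = 1) {
  lesion_shape <- match.arg(lesion_shape)
  stopifnot(n_patients >= 2, length(grid) == 3, all(grid >= 2),
            n_regions >= 1, n_regions <= prod(grid),
            territory_frac > 0, territory_frac <= 1,
            n_blobs >= 0, blob_size >= 0, n_negative_regions >= 0,
            hours_sd >= 0, noise_frac >= 0, is.null(noise_sd) || noise_sd >= 0,
            n_behavioural >= 0)
  structure(as.list(environment()), class = "generator_config")
}

# internal: sub-seeds for the generator stages, all derived from config$seed
generator_seeds <- function(config) {
  s <- spawn_seeds(config$seed, 5)
  list(atlas = s[1], lesions = s[2], covariates = s[3],
       behavioural = s[4], response = s[5])
}

#' Build the toy atlas
#'
#' Partitions the grid into `n_regions` contiguous regions: region seed
#' voxels are sampled uniformly and every voxel joins its nearest seed
#' (Voronoi cells; ties to the lowest region index). With
#' `overlap_atlas = TRUE` a second atlas of pairwise-union duplicate regions
#' is appended, mimicking the overlap between parcellations drawn from
#' different published atlases.
#'
#' @param config A `generator_config`.
#' @return A `region_set`.
#' @export
make_toy_atlas <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  gd <- config$grid
  nvox <- prod(gd)
  coords <- as.matrix(expand.grid(x = seq_len(gd[1]), y = seq_len(gd[2]),
                                  z = seq_len(gd[3])))
  centers <- withr::with_seed(generator_seeds(config)$atlas,
                              sort(sample.int(nvox, config$n_regions)))
  cc <- coords[centers, , drop = FALSE]
  # squared distance voxel -> center, nearest wins (first index on ties)
  d2 <- outer(rowSums(coords^2), rep(1, nrow(cc))) -
    2 * coords %*% t(cc) + outer(rep(1, nvox), rowSums(cc^2))
  assign <- max.col(-d2, ties.method = "first")
  fmt <- sprintf("R%%0%dd", max(2, nchar(config$n_regions)))
  regions <- lapply(seq_len(config$n_regions), function(i)
    list(region_id = sprintf(fmt, i), atlas_id = "toy1",
         voxels = which(assign == i)))
  if (isTRUE(config$overlap_atlas)) {
    n_dup <- min(5, config$n_regions - 1)
    dups <- lapply(seq_len(n_dup), function(i) {
      # union of a region with its nearest neighbouring region's voxels
      others <- setdiff(seq_len(config$n_regions), i)
      d <- colSums((t(cc[others, , drop = FALSE]) - cc[i, ])^2)
      j <- others[which.min(d)]
      list(region_id = sprintf(paste0("D", fmt), i), atlas_id = "toy2",
           voxels = sort(union(regions[[i]]$voxels, regions[[j]]$voxels)))
    })
    regions <- c(regions, dups)
  }
  rs <- region_set(regions, grid_dim = gd)
  attr(rs, "centers") <- cc
  rs
}

# internal: grow one contiguous blob by a voxel random walk inside bounds
grow_blob <- function(seed_voxel, size, gd, x_max) {
  if (size <= 0) return(integer(0))
  visited <- seed_voxel
  attempts <- 0
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  coords <- matrix(arrayInd(seed_voxel, gd), 1)
  while (length(visited) < size && attempts < size * 25) {
    attempts <- attempts + 1
    i <- sample.int(length(visited), 1)
    nb <- coords[i, ] + offsets[sample.int(6, 1), ]
    if (nb[1] < 1 || nb[1] > x_max || nb[2] < 1 || nb[2] > gd[2] ||
        nb[3] < 1 || nb[3] > gd[3]) next
    idx <- nb[1] + (nb[2] - 1) * gd[1] + (nb[3] - 1) * gd[1] * gd[2]
    if (!(idx %in% visited)) {
      visited <- c(visited, idx)
      coords <- rbind(coords, nb)
    }
  }
  visited
}

# internal: solid sphere of approximately `size` voxels inside bounds
sphere_blob <- function(seed_voxel, size, gd, x_max) {
  if (size <= 0) return(integer(0))
  ctr <- arrayInd(seed_voxel, gd)[1, ]
  radius <- max(1, (3 * size / (4 * pi))^(1 / 3))
  rng <- function(c0, lim) max(1, floor(c0 - radius)):min(lim, ceiling(c0 + radius))
  g <- expand.grid(x = rng(ctr[1], x_max), y = rng(ctr[2], gd[2]),
                   z = rng(ctr[3], gd[3]))
  keep <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  g$x + (g$y - 1) * gd[1] + (g$z - 1) * gd[1] * gd[2]
}

#' Simulate per-patient lesion masks
#'
#' Each patient receives a union of contiguous blobs seeded near two lesion
#' foci inside the designated territory (the first `territory_frac` of the
#' grid's x axis). A patient-specific mixing proportion decides how much of
#' the lesion sits near focus A versus focus B, so loads near A
#' anticorrelate with loads near B across the cohort while most territory
#' regions are damaged in most patients; regions wholly outside the
#' territory are never damaged.
#'
#' @param config A `generator_config`.
#' @param atlas The `region_set` from [make_toy_atlas()] (used only for its
#'   grid and space tag).
#' @return List of `lesion_mask` objects with attributes `blob_centers` and
#'   `focus_assignment` (each patient's focus-A mixing proportion).
#' @export
make_lesions <- function(config, atlas) {
  stopifnot(inherits(config, "generator_config"), inherits(atlas, "region_set"))
  gd <- config$grid
  x_max <- max(1, ceiling(gd[1] * config$territory_frac))
  foci <- lesion_foci(config)
  n <- config$n_patients
  withr::with_seed(generator_seeds(config)$lesions, {
    # each patient draws a mixing proportion: how much of their lesion sits
    # near focus A versus focus B; the U-shaped Beta keeps the two load
    # blocks strongly anticorrelated across the cohort while still hitting
    # most territory regions in most patients
    focus_mix <- stats::rbeta(n, 0.7, 0.7)
    centers <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      grid_arr <- array(0L, dim = gd)
      ctrs <- matrix(NA_real_, 0, 3)
      # stroke volumes are heavy-tailed and patient-level: one severity
      # factor scales all of a patient's blobs, so neighbouring regions are
      # damaged together and their loads correlate positively
      severity <- exp(stats::rnorm(1, 0, 0.35))
      for (b in seq_len(config$n_blobs)) {
        size <- if (config$blob_size <= 0) 0
                else round(config$blob_size * severity *
                             exp(stats::rnorm(1, 0, 0.25)))
        focus <- if (stats::runif(1) < focus_mix[i]) 1L else 2L
        ctr <- round(foci[focus, ] + stats::rnorm(3, 0, 2.5))
        ctr <- pmin(pmax(ctr, 1), c(x_max, gd[2], gd[3]))
        ctrs <- rbind(ctrs, ctr)
        if (size <= 0) next
        seed_voxel <- ctr[1] + (ctr[2] - 1) * gd[1] + (ctr[3] - 1) * gd[1] * gd[2]
        vox <- if (config$lesion_shape == "walk")
          grow_blob(seed_voxel, size, gd, x_max)
        else sphere_blob(seed_voxel, size, gd, x_max)
        grid_arr[vox] <- 1L
      }
      centers[[i]] <- ctrs
      masks[[i]] <- lesion_mask(sprintf("P%02d", i), grid_arr,
                                space_tag = atlas$space_tag)
    }
    structure(masks, blob_centers = centers,
              focus_assignment = focus_mix)
  })
}

# internal: the two lesion foci, both inside the territory
lesion_foci <- function(config) {
  gd <- config$grid
  x_max <- max(1, ceiling(gd[1] * config$territory_frac))
  rbind(A = c(round(x_max * 0.5), round(gd[2] * 0.3), round(gd[3] * 0.5)),
        B = c(round(x_max * 0.5), round(gd[2] * 0.7), round(gd[3] * 0.5)))
}

#' Planted ground-truth region weights
#'
#' The `n_negative_regions` regions whose centroids lie nearest focus A
#' receive `weight_scale` (negative by default: damage there reduces the
#' treatment response); all other regions get zero. Because focus-B damage
#' implies focus-A sparing, zero-weight regions near focus B acquire
#' positive *apparent* influence, the planted analogue of the proxy-region
#' effect.
#'
#' @param config A `generator_config`.
#' @param atlas The `region_set` from [make_toy_atlas()].
#' @return Named numeric vector of planted weights over all atlas regions.
#' @export
planted_weights <- function(config, atlas) {
  ids <- region_ids(atlas)
  w <- stats::setNames(rep(0, length(ids)), ids)
  if (config$n_negative_regions > 0) {
    cents <- t(vapply(atlas$regions, function(r)
      colMeans(arrayInd(r$voxels, atlas$grid_dim)), numeric(3)))
    fA <- lesion_foci(config)["A", ]
    d <- colSums((t(cents) - fA)^2)
    k <- min(config$n_negative_regions, length(ids))
    w[order(d)[seq_len(k)]] <- config$weight_scale
  }
  w
}

#' Generate treatment responses from planted structure
#'
#' `y = intercept + loads %*% w + beta_hours * hours +
#'  beta_interaction * hours * (loads %*% w) + noise`, with
#' `noise ~ N(0, noise_sd^2)` and `noise_sd` defaulting to
#' `noise_frac * sd(noiseless signal)`.
#'
#' @param config A `generator_config`.
#' @param loads Patients x regions load matrix (named columns) or a
#'   `lesion_load_matrix`.
#' @param hours Numeric therapy-hours vector.
#' @param weights Planted region weights; default [planted_weights()] needs
#'   the atlas, so pass the vector produced there (names matched to the
#'   load columns; absent regions contribute zero).
#' @return List with `response`, `noiseless`, `noise`, `noise_sd` and the
#'   `weights` used.
#' @export
make_responses <- function(config, loads, hours, weights) {
  M <- if (inherits(loads, "lesion_load_matrix")) loads$values else as.matrix(loads)
  stopifnot(nrow(M) == length(hours))
  w <- stats::setNames(rep(0, ncol(M)), colnames(M))
  shared <- intersect(names(weights), colnames(M))
  w[shared] <- weights[shared]
  lesion_term <- unname(drop(M %*% w))
  noiseless <- config$response_intercept + lesion_term +
    config$beta_hours * hours +
    config$beta_interaction * hours * lesion_term
  noise_sd <- if (!is.null(config$noise_sd)) config$noise_sd
              else config$noise_frac * stats::sd(noiseless)
  noise <- withr::with_seed(generator_seeds(config)$response,
                            stats::rnorm(length(hours), 0, noise_sd))
  y <- noiseless + noise
  if (isTRUE(config$round_response)) y <- round(y)
  list(response = y, noiseless = noiseless, noise = noise,
       noise_sd = noise_sd, weights = weights)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the whole generator: toy atlas, lesion masks, lesion-load encoding
#' (all-zero regions pruned), demographics, initial naming severity (worse
#' with more damage in the planted-negative regions), therapy hours,
#' behavioural scores (noisy mixtures of lesion loads), and responses from
#' the planted weight map. Fully reproducible from the config's seed.
#'
#' @param config A `generator_config` (default `synthetic_config()`).
#' @return Object of class `synthetic_cohort`: fields `cohort`
#'   (an [cohort()] with blocks `demographics`, `initial_severity`, `hours`,
#'   `behavioural`, `lesions`), `loads` (the `lesion_load_matrix`), `atlas`,
#'   `masks`, and `truth` (planted weights, noiseless responses, noise,
#'   noise sd, blob centers, focus assignment).
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "generator_config"))
  atlas <- make_toy_atlas(config)
  masks <- make_lesions(config, atlas)
  loads <- encode_cohort(masks, atlas, drop_zero_variance = TRUE)
  n <- config$n_patients
  w <- planted_weights(config, atlas)
  neg_regions <- intersect(names(w)[w != 0], loads$region_ids)
  dmg <- if (length(neg_regions))
    rowMeans(loads$values[, neg_regions, drop = FALSE]) else rep(0, n)
  cov_seed <- generator_seeds(config)$covariates
  covs <- withr::with_seed(cov_seed, {
    list(age = round(stats::rnorm(n, 61, 11), 1),
         sex = stats::rbinom(n, 1, 0.5),
         months_post_stroke = round(exp(stats::rnorm(n, log(40), 0.6))),
         hours = pmax(1, stats::rnorm(n, config$hours_mean, config$hours_sd)),
         severity_noise = stats::rnorm(n, 0, 0.08))
  })
  initial <- round(pmin(pmax(
    150 * (0.45 - 0.5 * dmg + covs$severity_noise), 0), 150))
  behavioural <- withr::with_seed(generator_seeds(config)$behavioural, {
    p <- ncol(loads$values)
    if (config$n_behavioural == 0) {
      matrix(numeric(0), n, 0)
    } else {
      mix <- matrix(stats::rnorm(p * config$n_behavioural), p) *
        matrix(stats::rbinom(p * config$n_behavioural, 1, 0.25), p)
      raw <- scale(loads$values) %*% mix +
        matrix(stats::rnorm(n * config$n_behavioural), n)
      sc <- apply(raw, 2, stats::sd)
      sc[sc == 0] <- 1
      out <- 50 + 10 * sweep(sweep(raw, 2, colMeans(raw), "-"), 2, sc, "/")
      colnames(out) <- sprintf("score%02d", seq_len(config$n_behavioural))
      round(out, 1)
    }
  })
  resp <- make_responses(config, loads, covs$hours, w)
  coh <- cohort(
    patient_ids = loads$patient_ids,
    blocks = list(
      demographics = cbind(age = covs$age, sex = covs$sex,
                           months_post_stroke = covs$months_post_stroke),
      initial_severity = matrix(initial, ncol = 1,
                                dimnames = list(NULL, "initial_naming")),
      hours = matrix(covs$hours, ncol = 1, dimnames = list(NULL, "hours")),
      behavioural = behavioural,
      lesions = loads$values),
    response = resp$response)
  structure(
    list(cohort = coh, loads = loads, atlas = atlas, masks = masks,
         config = config,
         truth = list(weights = w, noiseless = resp$noiseless,
                      noise = resp$noise, noise_sd = resp$noise_sd,
                      blob_centers = attr(masks, "blob_centers"),
                      focus_assignment = attr(masks, "focus_assignment"))),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d/%d regions retained, noise sd %.2f (seed %d)\n",
              n_patients(x$cohort), ncol(x$loads$values),
              length(x$atlas$regions), x$truth$noise_sd, x$config$seed))
  invisible(x)
}
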