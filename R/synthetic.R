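#' Phantom specification
#'
#' Describes a desk-scale stand-in for a registered, segmented brain: a
#' grid, a background tissue level and a set of geometric regions (spheres
#' or boxes) with their own tissue levels. Regions are the units that carry
#' shared across-subject variability and group effects, so the phantom has
#' strong within-region and weak across-region neighbor correlations once
#' subjects are simulated.
#'
#' @param grid_shape length-3 integer grid size.
#' @param voxel_size_mm mm per axis (scalar or length 3).
#' @param regions list of regions, each a list with `label` (integer > 0),
#'   `shape` (`"sphere"` or `"box"`), `center` (voxel, 1-based), `radius`
#'   (voxels, spheres) or `half_width` (voxels, boxes), and `tissue`
#'   (level in \[0, 1\]).
#' @param background background tissue level in \[0, 1\].
#' @param boundary_sigma_mm smoothing applied to the tissue map so region
#'   boundaries are soft.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), voxel_size_mm = 2,
                         regions = default_regions(),
                         background = 0, boundary_sigma_mm = 2) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("'grid_shape' must be 3 integers >= 4")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (background < 0 || background > 1)
    stop("'background' must lie in [0, 1]")
  for (r in regions) {
    if (any(r$center < 1) || any(r$center > grid_shape))
      stop("region ", r$label, " center outside the grid")
    if (r$tissue < 0 || r$tissue > 1)
      stop("region ", r$label, " tissue level outside [0, 1]")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 regions = regions, background = background,
                 boundary_sigma_mm = boundary_sigma_mm),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @details `default_regions()` places six spheres of radius 4 voxels on a
#'   32^3 grid, well separated by background so that the template shows
#'   within-region correlation without cross-region bridges.
#' @export
default_regions <- function() {
  centers <- rbind(c(9, 9, 9), c(24, 9, 9), c(9, 24, 9),
                   c(24, 24, 9), c(9, 16, 24), c(24, 16, 24))
  lapply(seq_len(nrow(centers)), function(i)
    list(label = i, shape = "sphere", center = centers[i, ], radius = 4,
         tissue = 0.9))
}

#' Build a phantom tissue map and region labels
#'
#' Deterministically rasterizes the regions of a [phantom_spec] into an
#' integer label volume (later regions overwrite earlier ones, with a
#' warning on overlap) and a tissue-probability volume, smoothed by the
#' spec's boundary softness and clipped to \[0, 1\].
#'
#' @param spec a [phantom_spec].
#' @return List of class `phantom`: `tissue_prob` and `labels`
#'   ([volume_grid]s), plus the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  affine <- diag(c(spec$voxel_size_mm, 1))
  labels <- array(0L, d)
  tissue <- array(spec$background, d)
  ii <- slice.index(labels, 1); jj <- slice.index(labels, 2)
  kk <- slice.index(labels, 3)
  for (r in spec$regions) {
    inside <- if (identical(r$shape, "sphere")) {
      (ii - r$center[1])^2 + (jj - r$center[2])^2 +
        (kk - r$center[3])^2 <= r$radius^2
    } else if (identical(r$shape, "box")) {
      abs(ii - r$center[1]) <= r$half_width[1] &
        abs(jj - r$center[2]) <= r$half_width[min(2, length(r$half_width))] &
        abs(kk - r$center[3]) <= r$half_width[min(3, length(r$half_width))]
    } else stop("unknown region shape: ", r$shape)
    if (any(labels[inside] != 0L))
      warning("region ", r$label, " overlaps an earlier region; ",
              "later region wins")
    labels[inside] <- as.integer(r$label)
    tissue[inside] <- r$tissue
  }
  tissue <- gaussian_smooth(tissue, spec$boundary_sigma_mm,
                            spec$voxel_size_mm)
  tissue <- pmin(pmax(tissue, 0), 1)
  structure(list(tissue_prob = volume_grid(tissue, affine = affine),
                 labels = volume_grid(labels + 0, affine = affine),
                 spec = spec),
            class = "phantom")
}

#' Simulation parameters for multi-subject volumes
#'
#' @param n_subjects number of simulated subjects (>= 4).
#' @param latent_weight strength of the per-subject, per-region shared
#'   factor in \[0, 1\] (drives within-region correlation).
#' @param noise_sigma standard deviation of the voxelwise white noise
#'   (> 0), added before smoothing.
#' @param smoothing_sigma_mm Gaussian smoothing applied to each subject
#'   volume, mm (matches the smoothing of real segment preprocessing).
#' @param voxel_noise_sigma standard deviation of a voxel-scale residual
#'   added after smoothing (>= 0). Without it, smoothing leaves adjacent
#'   voxels almost perfectly correlated everywhere (neighbor correlations
#'   above 0.95 even in pure-noise background), which no real segment data
#'   shows; the default puts within-region neighbor correlations near 0.9
#'   and background correlations near 0.
#' @param seed root seed; per-subject streams are derived from it.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 120, latent_weight = 0.6,
                              noise_sigma = 0.4, smoothing_sigma_mm = 4,
                              voxel_noise_sigma = 0.1, seed = 1) {
  if (n_subjects < 4) stop("'n_subjects' must be >= 4")
  if (latent_weight < 0 || latent_weight > 1)
    stop("'latent_weight' must lie in [0, 1]")
  if (noise_sigma <= 0) stop("'noise_sigma' must be positive")
  if (voxel_noise_sigma < 0) stop("'voxel_noise_sigma' must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 latent_weight = latent_weight, noise_sigma = noise_sigma,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 voxel_noise_sigma = voxel_noise_sigma,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate registered, smoothed subject volumes on a phantom
#'
#' Each subject's volume emulates a registered, smoothed tissue-density
#' segment: a baseline of 1 plus `latent_weight * z[subject, region]`
#' inside each region (one standard-normal factor per subject and region)
#' plus white Gaussian noise of SD `noise_sigma` everywhere, Gaussian
#' smoothed; a voxel-scale residual of SD `voxel_noise_sigma` is then
#' added, and the result is scaled by the phantom tissue probability and
#' clamped to \[0, 1\]. The across-subject mean is therefore approximately the tissue
#' probability itself (as for real segments), while the latent factors
#' drive strong within-region neighbor correlations. Deterministic per
#' seed, with per-subject derived streams: subject i is identical
#' regardless of `n_subjects >= i`.
#'
#' @param phantom a [make_phantom] result.
#' @param params a [simulation_params].
#' @return List of `n_subjects` [volume_grid]s.
#' @export
simulate_subjects <- function(phantom, params) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(params, "simulation_params"))
  labels <- phantom$labels$data
  tissue <- phantom$tissue_prob$data
  voxmm <- phantom$tissue_prob$voxel_size
  region_ids <- sort(unique(labels[labels > 0]))
  region_vox <- lapply(region_ids, function(r) which(labels == r))
  out <- vector("list", params$n_subjects)
  for (s in seq_len(params$n_subjects)) {
    set.seed((params$seed * 1000003L + s * 7919L) %% .Machine$integer.max)
    vol <- 1 + array(stats::rnorm(length(labels), sd = params$noise_sigma),
                     dim(labels))
    z <- stats::rnorm(length(region_ids))
    for (r in seq_along(region_ids))
      vol[region_vox[[r]]] <- vol[region_vox[[r]]] +
        params$latent_weight * z[r]
    vol <- gaussian_smooth(vol, params$smoothing_sigma_mm, voxmm)
    if (params$voxel_noise_sigma > 0)
      vol <- vol + array(stats::rnorm(length(labels),
                                      sd = params$voxel_noise_sigma),
                         dim(labels))
    vol <- pmin(pmax(vol * tissue, 0), 1)
    out[[s]] <- volume_grid(vol, affine = phantom$tissue_prob$affine)
  }
  out
}

#' Inject a localized group effect into simulated volumes
#'
#' Adds `d` times the pooled within-region across-subject SD to the
#' volumes of group-1 subjects inside the given region, so the realized
#' voxelwise Cohen's d in the region is approximately `d`. Voxels outside
#' the region are untouched.
#'
#' @param volumes list of [volume_grid]s.
#' @param labels region-label [volume_grid] (from [make_phantom]).
#' @param region region label to modify.
#' @param d target effect size.
#' @param group_assignment 0/1 vector over subjects; group 1 receives the
#'   effect.
#' @return The modified list of volumes.
#' @export
inject_group_effect <- function(volumes, labels, region, d,
                                group_assignment) {
  if (length(group_assignment) != length(volumes))
    stop("'group_assignment' length must match the number of volumes")
  vox <- which(labels$data == region)
  if (!length(vox)) stop("unknown region label: ", region)
  if (d == 0) return(volumes)
  vals <- vapply(volumes, function(v) v$data[vox],
                 numeric(length(vox)))          # vox x subjects
  sds <- apply(vals, 1, stats::sd)
  delta <- d * mean(sds)
  for (s in which(group_assignment == 1)) {
    volumes[[s]]$data[vox] <- volumes[[s]]$data[vox] + delta
  }
  volumes
}

#' Packaged synthetic validation dataset
#'
#' Builds the full stated world of the desk-scale validation: the default
#' six-region 32^3 phantom, `n_subjects` simulated subjects, `k` balanced
#' orthogonal splits, and one injected regional group effect per split
#' (split j's group 1 gains an effect of size `d` in region j). Because the
#' splits are orthogonal, each split sees only its own region's effect as a
#' between-group mean difference; the other splits' effects contribute
#' variance, mimicking between-group anatomical variability.
#'
#' @param n_subjects number of subjects (default 120, split 60/60).
#' @param k number of orthogonal splits (default 6; requires as many
#'   regions in the phantom).
#' @param d injected effect size per split region (default 1.0).
#' @param seed root seed.
#' @param spec phantom specification.
#' @param params simulation parameters (its seed is overridden by `seed`).
#' @return List with `phantom`, `volumes`, `splits` (a `split_plan`),
#'   `effect_d`, `effect_regions`.
#' @export
simulate_validation_dataset <- function(n_subjects = 120, k = 6, d = 1.0,
                                        seed = 1,
                                        spec = phantom_spec(),
                                        params = simulation_params(
                                          n_subjects = n_subjects,
                                          seed = seed)) {
  phantom <- make_phantom(spec)
  region_ids <- sort(unique(phantom$labels$data[phantom$labels$data > 0]))
  if (length(region_ids) < k)
    stop("phantom has ", length(region_ids), " regions but ", k,
         " splits were requested")
  volumes <- simulate_subjects(phantom, params)
  splits <- orthogonal_splits(length(volumes), k, seed = seed)
  for (j in seq_len(k)) {
    volumes <- inject_group_effect(volumes, phantom$labels, region_ids[j],
                                   d, splits$assignments[j, ])
  }
  list(phantom = phantom, volumes = volumes, splits = splits,
       effect_d = d, effect_regions = region_ids[seq_len(k)])
}
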