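#' Kernel configuration
#'
#' Bundles the parameters of the (an)isotropic Gaussian kernel: the
#' full-width at half-maximum of the Gaussian, the degree of anisotropy
#' `alpha` (0 = classical isotropic kernel, 1 = fully correlation-driven
#' distances), the tissue-probability attenuation threshold, and the
#' propagation cutoff (deformed distances strictly greater than the cutoff
#' receive no kernel value; at the default cutoff = FWHM the last included
#' value is the peak effect divided by 16, already negligible).
#'
#' @param fwhm_mm kernel full-width at half-maximum in mm (> 0).
#' @param alpha degree of anisotropy in \[0, 1\].
#' @param tissue_threshold attenuation threshold (see [attenuate]).
#' @param cutoff_mm maximum deformed path distance; default `fwhm_mm`.
#' @return An object of class `kernel_config` with the derived
#'   `sigma_mm`.
#' @export
kernel_config <- function(fwhm_mm = 20, alpha = 1, tissue_threshold = 0.1,
                          cutoff_mm = fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("'fwhm_mm' must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]")
  if (cutoff_mm <= 0) stop("'cutoff_mm' must be positive")
  structure(list(fwhm_mm = fwhm_mm, sigma_mm = sigma_from_fwhm(fwhm_mm),
                 alpha = alpha, tissue_threshold = tissue_threshold,
                 cutoff_mm = cutoff_mm),
            class = "kernel_config")
}

#' Convert between Gaussian sigma and FWHM
#'
#' FWHM = 2 sqrt(2 ln 2) sigma, so sigma is approximately 0.425 FWHM
#' (sigma = 8.5 mm for the default 20 mm kernel).
#'
#' @param fwhm_mm,sigma_mm positive values (vectorized).
#' @return The converted value(s).
#' @export
sigma_from_fwhm <- function(fwhm_mm) {
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm <= 0))
    stop("'fwhm_mm' must be positive")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

#' @rdname sigma_from_fwhm
#' @export
fwhm_from_sigma <- function(sigma_mm) {
  if (any(!is.finite(sigma_mm)) || any(sigma_mm <= 0))
    stop("'sigma_mm' must be positive")
  sigma_mm * 2 * sqrt(2 * log(2))
}

#' Un-normalised Gaussian kernel value
#'
#' The effect size assigned to a voxel at (deformed) distance `D` from a
#' peak of effect size `d_peak`: `exp(-D^2 / (2 sigma^2)) * d_peak`.
#' Strictly decreasing in `D`, sign-preserving; at `D = FWHM` the value is
#' exactly `d_peak / 16`. Infinite distances give 0.
#'
#' @param d_mm distance(s) in mm, >= 0 (`Inf` allowed).
#' @param sigma_mm kernel standard deviation (> 0).
#' @param d_peak peak effect size.
#' @return Kernel value(s).
#' @export
gaussian_value <- function(d_mm, sigma_mm, d_peak) {
  if (any(sigma_mm <= 0)) stop("'sigma_mm' must be positive")
  if (any(!is.na(d_mm) & d_mm < 0)) stop("distances must be non-negative")
  w <- exp(-d_mm^2 / (2 * sigma_mm^2))
  w[is.infinite(d_mm)] <- 0
  w * d_peak
}

#' Deformed distance between two contiguous voxels
#'
#' Interpolates between the real Euclidean step and the fully
#' correlation-driven step:
#' `D = sqrt((1 - alpha) * D_real^2 + alpha * 2 sigma^2 * ln(1 / rho))`.
#' At `alpha = 1` the step depends only on the correlation (two perfectly
#' correlated voxels are at distance 0); at `alpha = 0` it is the Euclidean
#' distance and `rho` is ignored. For `alpha > 0`, non-positive or missing
#' correlations make the step infinite (no propagation support), and
#' correlations within 1e-12 of 1 are treated as exactly 1. Per step the
#' identity `exp(-D^2 / 2 sigma^2) = rho_iso^(1 - alpha) * rho^alpha`
#' holds, with `rho_iso = exp(-D_real^2 / 2 sigma^2)` the spatially
#' constant correlation equivalent to the isotropic kernel.
#'
#' @param rho correlation(s) between the two voxels.
#' @param sigma_mm kernel standard deviation (> 0).
#' @param alpha degree of anisotropy in \[0, 1\].
#' @param d_real_mm Euclidean distance between the voxel centers (> 0).
#' @return Step distance(s) in mm (possibly `Inf`).
#' @export
deformed_step <- function(rho, sigma_mm, alpha, d_real_mm) {
  if (any(sigma_mm <= 0)) stop("'sigma_mm' must be positive")
  if (any(alpha < 0) || any(alpha > 1)) stop("'alpha' must lie in [0, 1]")
  if (any(d_real_mm <= 0)) stop("'d_real_mm' must be positive")
  if (any(!is.na(rho) & rho > 1 + 1e-9))
    stop("correlation above 1: ", max(rho, na.rm = TRUE))
  rho <- pmin(rho, 1)
  iso <- (1 - alpha) * d_real_mm^2
  if (length(alpha) == 1L && alpha == 0)
    return(sqrt(iso + numeric(length(rho))))
  aniso <- ifelse(!is.na(rho) & rho > 0,
                  alpha * 2 * sigma_mm^2 * log(1 / pmax(rho, 1e-300)),
                  Inf)
  aniso[alpha == 0] <- 0
  sqrt(iso + aniso)
}

#' Shortest deformed distances from a seed voxel
#'
#' Runs Dijkstra's algorithm on the 26-connected voxel grid with edge
#' weights from [deformed_step]: for each edge the stored neighbor
#' correlation is looked up in the template (13-map storage resolved on the
#' fly), attenuated by the tissue probability of the edge's lower-tissue
#' endpoint (see [attenuate]), and combined with the Euclidean center
#' distance. Expansion stops beyond the cutoff; voxels whose shortest
#' deformed distance exceeds the cutoff (strictly) are `Inf`. Propagation
#' is not restricted to any tissue mask.
#'
#' @param template a [correlation_template].
#' @param seed 1-based voxel index, length 3.
#' @param config a [kernel_config].
#' @return A list of class `deformed_distance_field` with `seed` and
#'   `distance` (a [volume_grid], mm, `Inf` where unreached).
#' @export
propagate <- function(template, seed, config) {
  stopifnot(inherits(template, "correlation_template"),
            inherits(config, "kernel_config"))
  d <- dim(template$rho)[1:3]
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel (", paste(seed, collapse = ","),
         ") outside the ", paste(d, collapse = "x"), " grid")
  no <- template$offsets
  dist <- dijkstra_propagate_cpp(
    template$rho, template$tissue_prob$data, as.integer(d),
    as.numeric(template$voxel_size), no$offsets,
    as.integer(no$half_index), no$is_half,
    seed - 1L, config$sigma_mm, config$alpha, config$cutoff_mm,
    config$tissue_threshold)
  structure(list(seed = seed,
                 distance = volume_grid(array(dist, d),
                                        affine = template$affine,
                                        voxel_size = template$voxel_size)),
            class = "deformed_distance_field")
}

#' Recreate the effect-size map of a single peak
#'
#' Maps the peak's world coordinate to the nearest voxel, propagates
#' deformed distances from it, and applies the Gaussian kernel. The value
#' at the peak voxel equals the peak effect size; voxels beyond the cutoff
#' are 0.
#'
#' @param template a [correlation_template].
#' @param peak a [peak] (world mm coordinate + effect size `d`), or any
#'   list with `coord_mm` and `value`.
#' @param config a [kernel_config].
#' @param return_weight also return the unit-peak kernel weight map used
#'   for multi-peak combination.
#' @return A [volume_grid] of effect sizes; if `return_weight`, a list
#'   `(value, weight, seed)`.
#' @export
recreate_from_peak <- function(template, peak, config,
                               return_weight = FALSE) {
  seed <- nearest_voxel(template$tissue_prob, peak$coord_mm)
  fld <- propagate(template, seed, config)
  w <- gaussian_value(fld$distance$data, config$sigma_mm, 1)
  value <- volume_grid(w * peak$value, affine = template$affine,
                       voxel_size = template$voxel_size)
  if (!return_weight) return(value)
  list(value = value,
       weight = volume_grid(w, affine = template$affine,
                            voxel_size = template$voxel_size),
       seed = seed)
}

#' Combine per-peak maps with a weighted average
#'
#' Voxelwise `sum(w_i v_i) / sum(w_i)`, where `w_i` is each peak's
#' un-normalised Gaussian kernel factor `exp(-D_i^2 / 2 sigma^2)`. A voxel
#' near two peaks gets an effect size depending on both; a voxel reached by
#' a single peak reproduces that peak's kernel value exactly; voxels
#' reached by none are 0.
#'
#' @param per_peak_maps list of [volume_grid] value maps.
#' @param per_peak_weights list of matching weight maps.
#' @return A [volume_grid].
#' @export
combine_peak_maps <- function(per_peak_maps, per_peak_weights) {
  if (!length(per_peak_maps)) stop("no peak maps to combine")
  if (length(per_peak_maps) != length(per_peak_weights))
    stop("maps and weights differ in length")
  stop_if_geometry_differs(c(per_peak_maps, per_peak_weights), "peak maps")
  ref <- per_peak_maps[[1]]
  num <- array(0, dim(ref$data))
  den <- array(0, dim(ref$data))
  for (i in seq_along(per_peak_maps)) {
    w <- per_peak_weights[[i]]$data
    num <- num + w * per_peak_maps[[i]]$data
    den <- den + w
  }
  out <- ifelse(den > 0, num / den, 0)
  volume_grid(out, affine = ref$affine, voxel_size = ref$voxel_size)
}
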