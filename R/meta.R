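#' Peaks and studies
#'
#' A peak is a reported coordinate (MNI mm) with its statistic value; a
#' study is a set of peaks plus the group sizes needed to convert
#' t-statistics to effect sizes and to compute their variances. One-sample
#' designs use `n2 = 0`.
#'
#' @param coord_mm length-3 world coordinate in mm.
#' @param value t-statistic or effect size `d` (see `stat`).
#' @param stat `"t"` or `"d"`.
#' @return `peak`: an object of class `peak`; `study`: class `study`.
#' @export
peak <- function(coord_mm, value, stat = c("t", "d")) {
  stat <- match.arg(stat)
  coord_mm <- as.numeric(coord_mm)
  if (length(coord_mm) != 3L || any(!is.finite(coord_mm)))
    stop("'coord_mm' must be 3 finite numbers")
  if (!is.finite(value)) stop("'value' must be finite")
  structure(list(coord_mm = coord_mm, value = as.numeric(value),
                 stat = stat), class = "peak")
}

#' @rdname peak
#' @param study_id unique study identifier.
#' @param peaks list of `peak` objects (may be empty).
#' @param n1,n2 group sizes; `n2 = 0` marks a one-sample design.
#' @export
study <- function(study_id, peaks, n1, n2 = 0) {
  if (n1 < 2) stop("'n1' must be at least 2")
  if (n2 < 0 || (n2 > 0 && n2 < 2)) stop("'n2' must be 0 or at least 2")
  if (!all(vapply(peaks, inherits, TRUE, "peak")))
    stop("'peaks' must be a list of peak objects")
  structure(list(study_id = as.character(study_id), peaks = peaks,
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "study")
}

#' Convert a t-statistic to an effect size, and its variance
#'
#' Standard large-sample conversions: for two samples
#' `d = t sqrt(1/n1 + 1/n2)` with
#' `var(d) = 1/n1 + 1/n2 + d^2 / (2 (n1 + n2))`; for one sample
#' (`n2 = 0`) `d = t / sqrt(n1)` with `var(d) = 1/n1 + d^2 / (2 n1)`.
#'
#' @param t t-statistic(s) (vectorized).
#' @param n1,n2 group sizes (`n2 = 0` for one-sample).
#' @return `t_to_d`: effect size(s); `d_variance`: variance(s).
#' @export
t_to_d <- function(t, n1, n2 = 0) {
  check_group_sizes(n1, n2)
  if (n2 == 0) t / sqrt(n1) else t * sqrt(1 / n1 + 1 / n2)
}

#' @rdname t_to_d
#' @param d effect size(s).
#' @export
d_variance <- function(d, n1, n2 = 0) {
  check_group_sizes(n1, n2)
  if (n2 == 0) 1 / n1 + d^2 / (2 * n1)
  else 1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2))
}

check_group_sizes <- function(n1, n2) {
  if (!is.numeric(n1) || n1 < 2) stop("'n1' must be at least 2")
  if (!is.numeric(n2) || n2 < 0 || (n2 > 0 && n2 < 2))
    stop("'n2' must be 0 (one-sample) or at least 2")
  invisible(TRUE)
}

#' Recreate a study's effect-size and variance maps from its peaks
#'
#' Converts t-value peaks to effect sizes, recreates a map per peak with
#' the deformed-space Gaussian kernel, combines them with the weighted
#' average, and derives the voxelwise variance from the group sizes.
#' Recreation runs over the whole volume (for diagnostic purposes, e.g. to
#' check that recreated maxima match reported peaks outside the mask);
#' voxels outside the tissue mask (`tissue_prob < mask_threshold`) are then
#' discarded (`NA`). Peaks whose coordinate falls outside the volume are
#' skipped with a warning.
#'
#' @param study a [study].
#' @param template a [correlation_template].
#' @param config a [kernel_config].
#' @param mask_threshold tissue-probability mask level (default 0.1).
#' @param mask apply the tissue mask (set `FALSE` for whole-volume maps).
#' @return A list of class `study_maps`: `effect`, `variance`
#'   ([volume_grid]s), `study_id`, `seeds` (one row per used peak).
#' @export
preprocess_study <- function(study, template, config, mask_threshold = 0.1,
                             mask = TRUE) {
  stopifnot(inherits(study, "study"))
  maps <- list(); weights <- list(); seeds <- NULL
  for (pk in study$peaks) {
    d_val <- if (pk$stat == "t") t_to_d(pk$value, study$n1, study$n2)
             else pk$value
    pk_d <- peak(pk$coord_mm, d_val, "d")
    rec <- tryCatch(
      recreate_from_peak(template, pk_d, config, return_weight = TRUE),
      error = function(e) {
        warning("study ", study$study_id, ": peak at (",
                paste(signif(pk$coord_mm, 6), collapse = ", "),
                ") skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(rec)) next
    maps[[length(maps) + 1L]] <- rec$value
    weights[[length(weights) + 1L]] <- rec$weight
    seeds <- rbind(seeds, rec$seed)
  }
  if (length(maps)) {
    effect <- combine_peak_maps(maps, weights)
  } else {
    effect <- volume_grid(array(0, dim(template$tissue_prob$data)),
                          affine = template$affine,
                          voxel_size = template$voxel_size)
  }
  variance <- effect
  variance$data <- d_variance(effect$data, study$n1, study$n2)
  if (mask) {
    out <- template$tissue_prob$data < mask_threshold
    effect$data[out] <- NA_real_
    variance$data[out] <- NA_real_
  }
  structure(list(effect = effect, variance = variance,
                 study_id = study$study_id, seeds = seeds),
            class = "study_maps")
}

#' Voxelwise random-effects combination of study maps
#'
#' DerSimonian-Laird method-of-moments estimate of the between-study
#' variance tau^2 per voxel, inverse-variance weights `1 / (var_i + tau^2)`,
#' pooled effect, its standard error and z-value. Voxels where any study is
#' masked (`NA`) are `NA` in the result.
#'
#' @param studies list of `study_maps` (from [preprocess_study]), one per
#'   study, identical geometry.
#' @return A list of class `meta_result` with [volume_grid]s
#'   `pooled_effect`, `tau2`, `se`, `z`, and `k` (number of studies).
#' @export
random_effects_combine <- function(studies) {
  if (!length(studies)) stop("no studies to combine")
  effs <- lapply(studies, `[[`, "effect")
  vars <- lapply(studies, `[[`, "variance")
  stop_if_geometry_differs(c(effs, vars), "study maps")
  ref <- effs[[1]]
  k <- length(studies)
  nvox <- length(ref$data)
  dmat <- vapply(effs, function(v) as.numeric(v$data), numeric(nvox))
  vmat <- vapply(vars, function(v) as.numeric(v$data), numeric(nvox))
  dmat <- matrix(dmat, nvox, k)
  vmat <- matrix(vmat, nvox, k)
  if (any(!is.na(vmat) & vmat <= 0)) stop("variances must be positive")

  w <- 1 / vmat
  sw <- rowSums(w)
  dbar <- rowSums(w * dmat) / sw
  if (k > 1) {
    q <- rowSums(w * (dmat - dbar)^2)
    cfac <- sw - rowSums(w^2) / sw
    tau2 <- pmax(0, (q - (k - 1)) / cfac)
  } else {
    tau2 <- numeric(nvox)
    tau2[is.na(dbar)] <- NA_real_
  }
  wstar <- 1 / (vmat + tau2)
  swstar <- rowSums(wstar)
  pooled <- rowSums(wstar * dmat) / swstar
  se <- 1 / sqrt(swstar)
  z <- pooled / se

  as_grid <- function(x) volume_grid(array(x, dim(ref$data)),
                                     affine = ref$affine,
                                     voxel_size = ref$voxel_size)
  structure(list(pooled_effect = as_grid(pooled), tau2 = as_grid(tau2),
                 se = as_grid(se), z = as_grid(z), k = k),
            class = "meta_result")
}
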