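#' Correlation templates
#'
#' A correlation template stores, for every voxel, the across-subject
#' Pearson correlation with each of its 26 neighbors (as 13 unique offset
#' maps; see [neighbor_offsets]) together with a tissue-probability map used
#' to attenuate correlations outside the tissue. Templates are built once
#' from a set of registered, smoothed multi-subject volumes and reused for
#' any meta-analysis on the same grid.
#'
#' @param rho 4D array (x, y, z, 13), one map per canonical half offset;
#'   `NA` marks missing correlations (zero-variance series, grid edge).
#' @param tissue_prob [volume_grid] with values in \[0, 1\].
#' @param metadata list; `tissue` label, `n_subjects`,
#'   `smoothing_sigma_mm` are stored and round-tripped.
#' @return An object of class `correlation_template`.
#' @export
correlation_template <- function(rho, tissue_prob, metadata = list()) {
  stopifnot(is_volume_grid(tissue_prob))
  d <- dim(rho)
  if (length(d) != 4L || d[4] != 13L)
    stop("'rho' must be a 4D array with 13 offset maps, got ",
         paste(d, collapse = "x"))
  if (!all(d[1:3] == dim(tissue_prob$data)))
    stop("rho maps and tissue_prob have different shapes")
  bad <- !is.na(rho) & (rho < -1 - 1e-6 | rho > 1 + 1e-6)
  if (any(bad))
    stop("correlations outside [-1, 1]: range ",
         paste(signif(range(rho, na.rm = TRUE), 4), collapse = " .. "))
  rho[] <- pmin(pmax(rho, -1), 1)
  p <- tissue_prob$data
  if (any(!is.na(p) & (p < -1e-6 | p > 1 + 1e-6)))
    stop("tissue probabilities outside [0, 1]")
  tissue_prob$data[] <- pmin(pmax(p, 0), 1)
  structure(list(rho = rho, tissue_prob = tissue_prob,
                 offsets = neighbor_offsets(),
                 affine = tissue_prob$affine,
                 voxel_size = tissue_prob$voxel_size,
                 metadata = metadata),
            class = "correlation_template")
}

#' @export
print.correlation_template <- function(x, ...) {
  d <- dim(x$rho)
  cat(sprintf("<correlation_template> %dx%dx%d voxels, 13 offset maps\n",
              d[1], d[2], d[3]))
  md <- x$metadata
  if (length(md))
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                    collapse = ", "), "\n")
  invisible(x)
}

rowwise_pearson <- function(a, b) {
  n <- ncol(a)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums(a * a) - n * ma^2
  vb <- rowSums(b * b) - n * mb^2
  cab <- rowSums(a * b) - n * ma * mb
  den <- sqrt(pmax(va, 0) * pmax(vb, 0))
  tol <- n * 1e-24
  r <- ifelse(va > tol & vb > tol, cab / den, NA_real_)
  pmin(pmax(r, -1), 1)
}

#' Build a correlation template from multi-subject volumes
#'
#' For every voxel and each of the 13 canonical neighbor offsets, computes
#' the Pearson correlation across subjects between the voxel's values and
#' the neighbor's values. Voxels whose series (or whose neighbor's series)
#' has zero variance, and neighbors outside the grid, are marked missing.
#'
#' @param subject_volumes list of at least 3 [volume_grid]s on one grid.
#' @param tissue_prob optional tissue-probability [volume_grid]; when
#'   omitted it is computed from the same volumes with
#'   [tissue_probability] (values clipped into \[0, 1\]).
#' @param tissue label recorded in the metadata.
#' @param smoothing_sigma_mm smoothing applied to the tissue-probability
#'   average, in mm.
#' @return A [correlation_template].
#' @export
neighbor_correlations <- function(subject_volumes, tissue_prob = NULL,
                                  tissue = "unknown",
                                  smoothing_sigma_mm = 4) {
  if (length(subject_volumes) < 3L)
    stop("need at least 3 subject volumes, got ", length(subject_volumes))
  stop_if_geometry_differs(subject_volumes, "subject volumes")
  ref <- subject_volumes[[1]]
  d <- dim(ref$data)
  x4 <- array(NA_real_, c(d, length(subject_volumes)))
  for (s in seq_along(subject_volumes))
    x4[, , , s] <- subject_volumes[[s]]$data
  no <- neighbor_offsets()
  rho <- array(NA_real_, c(d, 13L))
  for (h in seq_len(13L)) {
    o <- no$unique_half[h, ]
    lo <- pmax(1L, 1L - o)
    hi <- pmin(d, d - o)
    if (any(lo > hi)) next  # grid too thin for this offset
    sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
    a <- x4[sx, sy, sz, , drop = FALSE]
    b <- x4[sx + o[1], sy + o[2], sz + o[3], , drop = FALSE]
    nb <- prod(dim(a)[1:3])
    r <- rowwise_pearson(matrix(a, nb), matrix(b, nb))
    rho[cbind(rep(sx, times = length(sy) * length(sz)),
              rep(rep(sy, each = length(sx)), times = length(sz)),
              rep(sz, each = length(sx) * length(sy)),
              h)] <- r
  }
  if (is.null(tissue_prob)) {
    clipped <- lapply(subject_volumes, function(v) {
      v$data[] <- pmin(pmax(v$data, 0), 1); v
    })
    tissue_prob <- tissue_probability(clipped, smoothing_sigma_mm)
  }
  correlation_template(rho, tissue_prob,
                       metadata = list(tissue = tissue,
                                       n_subjects = length(subject_volumes),
                                       smoothing_sigma_mm = smoothing_sigma_mm))
}

#' Smoothed average tissue-probability map
#'
#' Voxelwise mean of per-subject tissue probability/density maps, Gaussian
#' smoothed and clipped to \[0, 1\]. `smoothing_sigma_mm = 0` yields the
#' plain mean.
#'
#' @param subject_segmentations list of [volume_grid]s with values in
#'   \[0, 1\], identical geometry.
#' @param smoothing_sigma_mm smoothing standard deviation in mm.
#' @return A [volume_grid] with values in \[0, 1\].
#' @export
tissue_probability <- function(subject_segmentations, smoothing_sigma_mm = 4) {
  if (!length(subject_segmentations)) stop("no segmentations given")
  stop_if_geometry_differs(subject_segmentations, "segmentations")
  for (i in seq_along(subject_segmentations)) {
    v <- subject_segmentations[[i]]$data
    if (any(!is.na(v) & (v < -1e-6 | v > 1 + 1e-6)))
      stop("segmentation ", i, " has values outside [0, 1]")
  }
  d <- dim(subject_segmentations[[1]]$data)
  acc <- array(0, d)
  for (v in subject_segmentations) acc <- acc + v$data
  acc <- acc / length(subject_segmentations)
  ref <- subject_segmentations[[1]]
  sm <- gaussian_smooth(acc, smoothing_sigma_mm, ref$voxel_size)
  volume_grid(pmin(pmax(sm, 0), 1), affine = ref$affine,
              voxel_size = ref$voxel_size)
}

#' Tissue-probability attenuation of correlations
#'
#' Below the tissue threshold (default 0.1), correlations are reduced
#' proportionally to the tissue probability: a correlation at tissue
#' probability `threshold / k` is divided by `k` (e.g. divided by 2 at
#' 0.05 and by 10 at 0.01 for the default threshold). At or above the
#' threshold correlations pass unchanged; zero tissue probability yields
#' zero. Continuous at the threshold.
#'
#' @param rho correlation value(s) in \[-1, 1\] (vectorized).
#' @param tissue_p tissue probability value(s) in \[0, 1\].
#' @param threshold attenuation threshold, non-negative.
#' @return Attenuated correlations, same shape as `rho`.
#' @examples
#' attenuate(0.8, 0.05)  # 0.4
#' attenuate(0.5, 0.01)  # 0.05
#' @export
attenuate <- function(rho, tissue_p, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single non-negative number")
  if (threshold == 0) return(rho)
  factor <- pmin(tissue_p / threshold, 1)
  rho * factor
}

#' Query the correlation of a voxel with any of its 26 neighbors
#'
#' Resolves the 13-map storage: for a canonical offset the value is read at
#' the voxel itself; for a negated offset it is read at the displaced voxel
#' under the canonical representative. Out-of-grid neighbors return `NA`.
#'
#' @param template a [correlation_template].
#' @param ijk 1-based voxel index, length 3.
#' @param offset integer displacement, each component in \{-1, 0, 1\},
#'   not all zero.
#' @return The stored correlation, or `NA`.
#' @export
query_correlation <- function(template, ijk, offset) {
  no <- template$offsets
  row <- which(no$offsets[, 1] == offset[1] & no$offsets[, 2] == offset[2] &
               no$offsets[, 3] == offset[3])
  if (!length(row)) stop("not a 26-neighborhood offset: ",
                         paste(offset, collapse = ","))
  d <- dim(template$rho)[1:3]
  h <- no$half_index[row]
  at <- if (no$is_half[row]) ijk else ijk + offset
  if (any(at < 1L) || any(at > d)) return(NA_real_)
  template$rho[at[1], at[2], at[3], h]
}

#' Save / load a correlation template
#'
#' Writes `<prefix>_rho.nii.gz` (4D, 13 volumes in canonical offset order),
#' `<prefix>_tissue.nii.gz` and a JSON sidecar `<prefix>.json` recording the
#' offset order and metadata. Loading verifies the volume count and that
#' the sidecar's offset order matches the canonical order.
#'
#' @param template a [correlation_template].
#' @param prefix output path prefix.
#' @return `save_template`: the prefix, invisibly. `load_template`: a
#'   [correlation_template].
#' @export
save_template <- function(template, prefix) {
  stopifnot(inherits(template, "correlation_template"))
  write_nifti(paste0(prefix, "_rho.nii.gz"), template$rho, template$affine)
  write_volume(paste0(prefix, "_tissue.nii.gz"), template$tissue_prob)
  side <- c(template$metadata,
            list(offsets = unname(apply(template$offsets$unique_half, 1,
                                        as.integer, simplify = FALSE))))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_template
#' @export
load_template <- function(prefix) {
  side_path <- paste0(prefix, ".json")
  if (!file.exists(side_path))
    stop("missing template sidecar: ", side_path)
  side <- jsonlite::read_json(side_path)
  rho_img <- read_nifti(paste0(prefix, "_rho.nii.gz"))
  d <- dim(rho_img$data)
  if (length(d) != 4L || d[4] != 13L)
    stop("template rho stack has ", if (length(d) == 4L) d[4] else 1L,
         " volumes, expected 13")
  canonical <- neighbor_offsets()$unique_half
  got <- do.call(rbind, lapply(side$offsets, unlist))
  if (is.null(got) || !all(dim(got) == dim(canonical)) ||
      !all(got == canonical))
    stop("sidecar offset order does not match the canonical 13 offsets")
  tissue <- read_volume(paste0(prefix, "_tissue.nii.gz"))
  md <- side[setdiff(names(side), "offsets")]
  correlation_template(rho_img$data, tissue, metadata = md)
}
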