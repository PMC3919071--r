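#' 3D volume with a voxel-to-world affine
#'
#' A `volume_grid` is the package's basic spatial container: a 3D numeric
#' array together with a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in millimetres (MNI space throughout). The array may hold
#' effect sizes, t-statistics, tissue probabilities or correlations; `NA`
#' marks voxels where the quantity is undefined.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world-mm.
#'   Defaults to `diag(c(voxel_size, 1))` when only `voxel_size` is given.
#' @param voxel_size length-3 positive numeric, mm per axis. Derived from
#'   `affine` when omitted.
#' @return An object of class `volume_grid` with fields `data`, `affine`,
#'   `voxel_size`.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), voxel_size = c(2, 2, 2))
#' dim(v$data)
#' @export
volume_grid <- function(data, affine = NULL, voxel_size = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got dims: ",
         paste(dim(data), collapse = "x"))
  storage.mode(data) <- "double"
  if (is.null(affine)) {
    if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' is singular")
  if (is.null(voxel_size))
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 strictly positive values")
  structure(list(data = data, affine = affine, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %dx%dx%d voxels, %s mm\n", d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  rng <- suppressWarnings(range(x$data, na.rm = TRUE))
  cat(sprintf("  values in [%.4g, %.4g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$data))))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' @rdname volume_grid
#' @param x,y two `volume_grid` objects.
#' @export
same_geometry <- function(x, y) {
  all(dim(x$data) == dim(y$data)) &&
    max(abs(x$affine - y$affine)) < 1e-6
}

stop_if_geometry_differs <- function(vols, what = "volumes") {
  ref <- vols[[1]]
  for (i in seq_along(vols)) {
    if (!is_volume_grid(vols[[i]]))
      stop(what, "[", i, "] is not a volume_grid")
    if (!same_geometry(ref, vols[[i]]))
      stop(what, " have mismatched shape/affine (volume ", i,
           ": ", paste(dim(vols[[i]]$data), collapse = "x"),
           " vs ", paste(dim(ref$data), collapse = "x"), ")")
  }
  invisible(TRUE)
}

#' Convert between world (mm) and voxel coordinates
#'
#' Voxel indices are 0-based, following the NIfTI convention for affines.
#' `world_to_voxel` returns continuous 0-based voxel coordinates;
#' `nearest_voxel` additionally snaps to the nearest voxel, rounding halves
#' away from zero, and returns 1-based array indices.
#'
#' @param vol a `volume_grid`.
#' @param xyz numeric length-3 world coordinate in mm, or an n x 3 matrix.
#' @return `world_to_voxel`/`voxel_to_world`: coordinates with the same
#'   shape as the input. `nearest_voxel`: 1-based integer indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  m <- rbind(t(matrix(as.numeric(xyz), ncol = 3)), 1)
  out <- solve(vol$affine, m)[1:3, , drop = FALSE]
  if (is.matrix(xyz)) t(out) else as.numeric(out)
}

#' @rdname world_to_voxel
#' @param ijk0 0-based voxel coordinate(s), length-3 or n x 3.
#' @export
voxel_to_world <- function(vol, ijk0) {
  m <- rbind(t(matrix(as.numeric(ijk0), ncol = 3)), 1)
  out <- (vol$affine %*% m)[1:3, , drop = FALSE]
  if (is.matrix(ijk0)) t(out) else as.numeric(out)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @rdname world_to_voxel
#' @export
nearest_voxel <- function(vol, xyz) {
  v0 <- round_half_away(world_to_voxel(vol, xyz))
  idx <- as.integer(v0) + 1L
  d <- dim(vol$data)
  if (any(idx < 1L) || any(idx > d))
    stop(sprintf("coordinate (%s) maps to voxel (%s), outside the %s grid",
                 paste(signif(xyz, 6), collapse = ", "),
                 paste(idx, collapse = ", "),
                 paste(d, collapse = "x")))
  idx
}

linear_index <- function(dim3, ijk) {
  as.integer((ijk[3] - 1L) * dim3[1] * dim3[2] + (ijk[2] - 1L) * dim3[1] +
             ijk[1])
}
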