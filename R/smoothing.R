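# Separable Gaussian smoothing on the voxel grid. The kernel is truncated at
# 4 sigma per axis and the result is renormalised by the smoothed all-ones
# volume, so constants are preserved exactly up to the grid edge (equivalent
# to normalised convolution with zero padding).

conv_matrix_1d <- function(n, sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1L & idx <= n
    m[idx[ok], j] <- m[idx[ok], j] + k[ok]
  }
  m
}

smooth_axis <- function(arr, axis, sigma_vox) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dx <- dim(x)
  x <- matrix(x, nrow = dx[1])
  x <- conv_matrix_1d(dx[1], sigma_vox) %*% x
  aperm(array(x, dx), order(perm))
}

#' Gaussian smoothing of a 3D array or volume
#'
#' Smooths with an isotropic Gaussian of standard deviation `sigma_mm`
#' (truncated at 4 sigma), edge-renormalised so that a constant input is
#' returned unchanged. `sigma_mm = 0` is the identity.
#'
#' @param vol a [volume_grid] or 3D array.
#' @param sigma_mm kernel standard deviation in mm (>= 0).
#' @param voxel_size mm per axis; taken from `vol` when it is a
#'   `volume_grid`.
#' @return Same type as the input.
#' @export
gaussian_smooth <- function(vol, sigma_mm, voxel_size = NULL) {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm < 0)
    stop("'sigma_mm' must be a single non-negative number")
  if (is_volume_grid(vol)) {
    out <- vol
    out$data <- gaussian_smooth(vol$data, sigma_mm, vol$voxel_size)
    return(out)
  }
  if (sigma_mm == 0) return(vol)
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  arr <- vol
  wt <- array(1, dim(arr))
  for (ax in 1:3) {
    s <- sigma_mm / voxel_size[ax]
    arr <- smooth_axis(arr, ax, s)
    wt <- smooth_axis(wt, ax, s)
  }
  arr / wt
}
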