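#' Separable 3-D Gaussian smoothing
#'
#' Convolves a volume with an isotropic Gaussian kernel of the given full
#' width at half maximum, applied separably along each axis in voxel units
#' with `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis. The kernel is
#' truncated at 4 sigma and normalized to unit sum, with zero padding at
#' the lattice boundary, so an interior impulse response conserves mass.
#' `fwhm_mm = 0` returns the input unchanged.
#'
#' @param v a [volume()].
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @return smoothed [volume()].
#' @export
gaussian_smooth <- function(v, fwhm_mm = 6) {
  stopifnot(is_volume(v))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("fwhm_mm must be a non-negative scalar")
  if (fwhm_mm == 0) return(v)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size(v)  # voxel units
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  a <- vol_data(v)
  for (ax in 1:3) a <- conv_axis(a, kern, ax)
  volume_like(a, v)
}

# banded-matrix convolution of `a` along axis `ax` with zero padding
conv_axis <- function(a, kern, ax) {
  d <- dim(a)
  r <- (length(kern) - 1L) / 2L
  n <- d[ax]
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- kern[off + r + 1L]
  }
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = n)
  aperm(array(m, dim = d[perm]), order(perm))
}
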