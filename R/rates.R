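#' Fit voxel-wise rate maps from a divergence series
#'
#' Independent ordinary-least-squares fit, at every voxel, of the
#' divergence values on scan time: the slope map is the subject's rate map
#' (relative tissue expansion or contraction per year, with divergence
#' treated as log-volume change so slopes read as fractional change/year);
#' the intercept is fitted and returned (near zero under the mid-point
#' registration convention).
#'
#' @param divergence list with `times` (years, >= 2 distinct) and `maps`
#'   (list of congruent [volume()]s, one per time).
#' @return object of class `svd_ratemap`: `slope` and `intercept` volumes
#'   plus `n_timepoints`.
#' @export
fit_voxel_rates <- function(divergence) {
  times <- divergence$times
  maps <- divergence$maps
  stopifnot(length(times) == length(maps))
  if (length(times) < 2L || length(unique(times)) < 2L)
    stop("rate fitting needs >= 2 distinct time points")
  check_same_grid(maps)
  tc <- times - mean(times)
  denom <- sum(tc^2)
  arrs <- lapply(maps, vol_data)
  mean_map <- Reduce(`+`, arrs) / length(arrs)
  num <- Reduce(`+`, Map(function(a, w) (a - mean_map) * w, arrs, tc))
  slope <- num / denom
  intercept <- mean_map - slope * mean(times)
  structure(list(slope = volume_like(slope, maps[[1L]]),
                 intercept = volume_like(intercept, maps[[1L]]),
                 n_timepoints = length(times)),
            class = "svd_ratemap")
}

#' @export
print.svd_ratemap <- function(x, ...) {
  cat(sprintf("<svd_ratemap> %d time points, slope range [%.4g, %.4g] /y\n",
              x$n_timepoints, min(x$slope), max(x$slope)))
  invisible(x)
}

#' Tissue-weighted rate map
#'
#' Voxel-wise product of the rate-map slope with a tissue probability map,
#' confining the rate signal to the tissue class of interest.
#'
#' @param rate a [fit_voxel_rates()] rate map (or a slope [volume()]).
#' @param tissue tissue probability [volume()].
#' @return weighted [volume()].
#' @export
tissue_weighted_rate <- function(rate, tissue) {
  slope <- if (inherits(rate, "svd_ratemap")) rate$slope else rate
  check_same_grid(slope, tissue)
  volume_like(vol_data(slope) * vol_data(tissue), slope)
}

#' Warped-weighted-average smoothing
#'
#' Weight-normalized Gaussian smoothing,
#' `smooth(map * weight) / smooth(weight)`: averages a map under a spatial
#' weight (e.g. a warped tissue map) without diluting the signal into
#' unweighted regions. Voxels where the smoothed weight falls below `eps`
#' are masked out as `NA`.
#'
#' @param map [volume()] to smooth.
#' @param weight non-negative weight [volume()], not identically zero.
#' @param fwhm_mm Gaussian kernel FWHM in mm.
#' @param eps smoothed-weight support threshold.
#' @return smoothed [volume()] with `NA` outside the weight support.
#' @export
wwa_smooth <- function(map, weight, fwhm_mm = 6, eps = 1e-5) {
  check_same_grid(map, weight)
  w <- vol_data(weight)
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("weight is identically zero")
  num <- gaussian_smooth(volume_like(vol_data(map) * w, map), fwhm_mm)
  den <- gaussian_smooth(weight, fwhm_mm)
  dv <- vol_data(den)
  out <- vol_data(num) / dv
  out[dv < eps] <- NA_real_
  volume_like(out, map, allow_na = TRUE)
}

#' Mean rate over a region of interest
#'
#' @param rate a [fit_voxel_rates()] rate map (or slope [volume()]).
#' @param mask non-empty binary [volume()].
#' @return mean slope over in-mask voxels (per year).
#' @export
roi_mean_rate <- function(rate, mask) {
  slope <- if (inherits(rate, "svd_ratemap")) rate$slope else rate
  check_same_grid(slope, mask)
  idx <- vol_data(mask) > 0
  if (!any(idx)) stop("empty ROI mask")
  mean(vol_data(slope)[idx])
}
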