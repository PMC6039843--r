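#' Extract an in-mask feature matrix
#'
#' Flattens one volume per subject into a subjects x voxels matrix over the
#' voxels of a binary mask. Row order follows the input list; column order
#' is the deterministic column-major (lexicographic) voxel index of the
#' mask, so identical masks always yield identical column layouts.
#'
#' @param volumes named list (by subject id) of congruent [volume()]s.
#' @param mask binary [volume()] on the same grid, non-empty.
#' @return object of class `svd_features`: list with `values` (matrix with
#'   subject-id rownames), `mask`, and `voxel_idx` (linear indices).
#' @export
extract_features <- function(volumes, mask) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  check_same_grid(c(volumes, list(mask)))
  idx <- which(vol_data(mask) > 0)
  if (length(idx) == 0L) stop("empty feature mask")
  vals <- t(vapply(volumes, function(v) vol_data(v)[idx],
                   numeric(length(idx))))
  if (!is.null(names(volumes))) rownames(vals) <- names(volumes)
  if (any(!is.finite(vals))) stop("non-finite feature values in mask")
  structure(list(values = vals, mask = mask, voxel_idx = idx),
            class = "svd_features")
}

#' @export
print.svd_features <- function(x, ...) {
  cat(sprintf("<svd_features> %d subjects x %d in-mask voxels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# rebuild a volume from per-voxel statistics over the feature mask,
# filling out-of-mask voxels with `fill`
features_to_volume <- function(features, stat_values, fill = 0) {
  a <- array(fill, dim = dim(features$mask))
  a[features$voxel_idx] <- stat_values
  volume_like(a, features$mask, allow_na = anyNA(a))
}

#' Mean-tissue analysis mask
#'
#' The implicit VBM analysis mask: voxels whose mean value across subjects
#' exceeds a threshold (default 0.1), restricting the voxel-wise tests to
#' tissue actually present in the cohort.
#'
#' @param volumes list of congruent volumes.
#' @param threshold mean-value cutoff.
#' @return binary [volume()].
#' @export
mean_tissue_mask <- function(volumes, threshold = 0.1) {
  check_same_grid(volumes)
  acc <- Reduce(`+`, lapply(volumes, vol_data)) / length(volumes)
  volume_like((acc > threshold) * 1, volumes[[1L]])
}
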