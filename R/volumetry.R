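#' Tissue volume at a probability threshold
#'
#' Volume in mm^3 of the voxels whose tissue probability meets or exceeds
#' the threshold (count of voxels with value >= threshold times the voxel
#' volume). The whole-brain parameters use threshold 0.2 for GM, WM and
#' CSF; the WMH map is binarised at a per-subject threshold (default 0.5).
#'
#' @param map probability [volume()] with values in \[0, 1\].
#' @param threshold probability threshold in \[0, 1\].
#' @return volume in mm^3.
#' @export
tissue_volume <- function(map, threshold = 0.2) {
  stopifnot(is_volume(map))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a probability in [0, 1]")
  a <- vol_data(map)
  if (min(a, na.rm = TRUE) < 0 || max(a, na.rm = TRUE) > 1)
    stop("tissue map values must lie in [0, 1]")
  sum(a >= threshold, na.rm = TRUE) * voxel_volume_mm3(map)
}

#' Total cerebral and intracranial volume
#'
#' TCV is the sum of grey matter, white matter and WMH volumes; TIV is TCV
#' plus the CSF volume.
#'
#' @param gm_mm3,wm_mm3,wmh_mm3,csf_mm3 tissue volumes in mm^3.
#' @return list with `tcv_mm3` and `tiv_mm3`.
#' @export
total_volumes <- function(gm_mm3, wm_mm3, wmh_mm3, csf_mm3 = 0) {
  vals <- c(gm_mm3, wm_mm3, wmh_mm3, csf_mm3)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("tissue volumes must be non-negative")
  tcv <- gm_mm3 + wm_mm3 + wmh_mm3
  list(tcv_mm3 = tcv, tiv_mm3 = tcv + csf_mm3)
}

#' SVDp vascular-burden percentage
#'
#' The percentage ratio of WMH volume to total cerebral volume,
#' `100 * wmh / tcv`. Combining lesion load with atrophy in one marker
#' avoids the spurious regression of raw WMH volume that can occur when a
#' static lesion load sits inside a shrinking brain.
#'
#' @param wmh_mm3 WMH volume in mm^3.
#' @param tcv_mm3 total cerebral volume in mm^3 (> 0).
#' @return percentage.
#' @export
svdp <- function(wmh_mm3, tcv_mm3) {
  if (any(tcv_mm3 == 0)) stop("SVDp undefined: TCV is zero")
  stopifnot(all(wmh_mm3 >= 0), all(tcv_mm3 > 0))
  100 * wmh_mm3 / tcv_mm3
}

#' Annualized rate of change
#'
#' Ordinary-least-squares slope of a longitudinal series on time in years,
#' using all available time points.
#'
#' @param values numeric series.
#' @param times years from baseline, at least two distinct.
#' @return slope per year.
#' @export
annualized_rate <- function(values, times) {
  stopifnot(length(values) == length(times))
  if (length(times) < 2L || length(unique(times)) < 2L)
    stop("annualized rate needs >= 2 distinct time points")
  tc <- times - mean(times)
  sum(tc * (values - mean(values))) / sum(tc^2)
}

#' Whole-brain volumetric row for one subject
#'
#' Computes the whole-brain MRI parameters from one tissue set: tissue
#' volumes at threshold 0.2 (GM/WM/CSF), the WMH volume at the per-subject
#' binarisation threshold, lacune volume, TCV (= gm + wm + wmh, so the row
#' identity holds exactly with the binarised WMH volume), TIV and SVDp.
#'
#' @param tissues named list of volumes `gm`, `wm`, `csf`, `wmh` and
#'   optionally binary `lacunes`.
#' @param threshold probability threshold for GM/WM/CSF (default 0.2).
#' @param wmh_threshold per-subject WMH binarisation threshold (default 0.5).
#' @return one-row data frame (`gm_mm3`, `wm_mm3`, `csf_mm3`, `wmh_mm3`,
#'   `lacune_mm3`, `tcv_mm3`, `tiv_mm3`, `svdp_percent`).
#' @export
volumetrics_row <- function(tissues, threshold = 0.2, wmh_threshold = 0.5) {
  check_same_grid(tissues)
  gm <- tissue_volume(tissues$gm, threshold)
  wm <- tissue_volume(tissues$wm, threshold)
  csf <- tissue_volume(tissues$csf, threshold)
  wmh <- tissue_volume(tissues$wmh, wmh_threshold)
  lac <- if (!is.null(tissues$lacunes))
    sum(vol_data(tissues$lacunes) > 0) * voxel_volume_mm3(tissues$lacunes) else NA_real_
  tot <- total_volumes(gm, wm, wmh, csf)
  data.frame(gm_mm3 = gm, wm_mm3 = wm, csf_mm3 = csf, wmh_mm3 = wmh,
             lacune_mm3 = lac, tcv_mm3 = tot$tcv_mm3, tiv_mm3 = tot$tiv_mm3,
             svdp_percent = if (tot$tcv_mm3 > 0) svdp(wmh, tot$tcv_mm3) else NA_real_)
}

#' Volumetric table for a simulated cohort
#'
#' One [volumetrics_row()] per subject, keyed by id and joined with group.
#'
#' @param subjects list of `svd_subject` with tissue maps.
#' @param cohort matching [cohort_table()].
#' @inheritParams volumetrics_row
#' @return data frame, one row per subject.
#' @export
volumetrics_table <- function(subjects, cohort, threshold = 0.2,
                              wmh_threshold = 0.5) {
  rows <- lapply(subjects, function(s) {
    cbind(data.frame(id = s$id, stringsAsFactors = FALSE),
          volumetrics_row(s$tissues, threshold, wmh_threshold))
  })
  out <- do.call(rbind, rows)
  out$group <- cohort$subjects$group[match(out$id, cohort$subjects$id)]
  out
}
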