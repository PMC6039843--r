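#' Lacune overlap map
#'
#' Voxel-wise sum of binary lacune masks across subjects; the group overlap
#' maps and their difference localize where lacunes accumulate.
#'
#' @param masks non-empty list of binary [volume()]s on one grid.
#' @return count [volume()]; maximum is bounded by the number of subjects.
#' @export
overlap_map <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("overlap_map needs a non-empty list of binary masks")
  check_same_grid(masks)
  for (m in masks) {
    a <- vol_data(m)
    if (!all(a %in% c(0, 1))) stop("overlap_map input masks must be binary")
  }
  acc <- Reduce(`+`, lapply(masks, vol_data))
  volume_like(acc, masks[[1L]])
}

#' Atlas-ROI lacune incidence table
#'
#' For each atlas region and group, the percentage of subjects carrying a
#' lacune of more than `min_volume_mm3` (strictly) inside the region, the
#' preVaD minus non-convertor difference in percentage points, a flag for
#' differences at or beyond `flag_difference` points, and left/right
#' subject counts for the asymmetry summary.
#'
#' @param lacune_masks named list (by subject id) of binary lacune volumes.
#' @param atlas a [make_atlas()] atlas congruent with the masks.
#' @param groups factor/character of group labels aligned with
#'   `lacune_masks` (`"preVaD"` / `"non-convertor"`).
#' @param min_volume_mm3 minimum intersecting lacune volume; strict
#'   inequality, so a lacune of exactly this volume does not count.
#' @param flag_difference flag threshold in percentage points.
#' @return data frame, one row per region.
#' @export
roi_incidence <- function(lacune_masks, atlas, groups, min_volume_mm3 = 10,
                          flag_difference = 9) {
  stopifnot(length(lacune_masks) == length(groups))
  bad <- setdiff(unique(as.character(groups)), c("preVaD", "non-convertor"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  check_same_grid(c(lacune_masks, list(atlas$labels)))
  groups <- as.character(groups)
  labs <- vol_data(atlas$labels)
  vv <- voxel_volume_mm3(atlas$labels)
  # subject x region matrix of intersecting lacune volume
  inter <- vapply(lacune_masks, function(m) {
    a <- vol_data(m) > 0
    vapply(atlas$names, function(l) sum(a & labs == l) * vv, numeric(1))
  }, numeric(length(atlas$names)))
  present <- inter > min_volume_mm3        # strict: "more than"
  pct <- function(g) 100 * rowMeans(present[, groups == g, drop = FALSE])
  p_cv <- pct("preVaD"); p_nc <- pct("non-convertor")
  region <- names(atlas$names)
  side <- sub("^.*_", "", region)
  base <- sub("_[LR]$", "", region)
  out <- data.frame(region = region, base = base, side = side,
                    pct_prevad = p_cv, pct_nonconvertor = p_nc,
                    difference = p_cv - p_nc,
                    flagged = (p_cv - p_nc) >= flag_difference,
                    row.names = NULL)
  # left/right lacune-positive subject counts per base region
  cnt <- function(sd) vapply(unique(base), function(b) {
    r <- which(base == b & side == sd)
    sum(present[r, , drop = FALSE] > 0)
  }, numeric(1))
  asym <- data.frame(base = unique(base), n_left = cnt("L"), n_right = cnt("R"),
                     row.names = NULL)
  attr(out, "asymmetry") <- asym
  out
}

#' Rater-reliability report for paired volume measurements
#'
#' Reliability statistics for two raters' (or one rater's repeated) volume
#' series: the standard error of measurement `SD(a - b) / sqrt(2)`, the
#' mean percentage variability `100 * |a - b| / ((a + b) / 2)` with its SD,
#' a Pearson-based consistency ICC, and the two-way random absolute
#' agreement ICC(2,1) from the ANOVA mean squares. Pairs with `a + b == 0`
#' are dropped with a warning (their variability is undefined).
#'
#' @param volumes_a,volumes_b paired series in mm^3, at least 3 pairs.
#' @return object of class `svd_reliability` (a list of the metrics above).
#' @export
rater_reliability <- function(volumes_a, volumes_b) {
  stopifnot(length(volumes_a) == length(volumes_b))
  keep <- (volumes_a + volumes_b) != 0
  if (any(!keep))
    warning(sum(!keep), " pair(s) with a + b = 0 dropped")
  a <- volumes_a[keep]; b <- volumes_b[keep]
  if (length(a) < 3L) stop("rater_reliability needs >= 3 usable pairs")
  d <- a - b
  variability <- 100 * abs(d) / ((a + b) / 2)
  # two-way ANOVA mean squares for n subjects x k=2 raters
  n <- length(a); k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  ms_rows <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  ss_err <- sum((x - outer(rowMeans(x), rep(1, k)) -
                   outer(rep(1, n), colMeans(x)) + grand)^2)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc_a <- (ms_rows - ms_err) /
    (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)
  structure(list(
    n_pairs = n,
    sem_mm3 = stats::sd(d) / sqrt(2),
    mean_variability_percent = mean(variability),
    sd_variability_percent = stats::sd(variability),
    icc_consistency = stats::cor(a, b),
    icc_agreement = icc_a
  ), class = "svd_reliability")
}

#' @export
print.svd_reliability <- function(x, ...) {
  cat(sprintf(paste0("<svd_reliability> %d pairs: SEM %.3g mm^3, ",
                     "variability %.2f%% (SD %.2f), ICC consistency %.3f, ",
                     "ICC(2,1) agreement %.3f\n"),
              x$n_pairs, x$sem_mm3, x$mean_variability_percent,
              x$sd_variability_percent, x$icc_consistency, x$icc_agreement))
  invisible(x)
}
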