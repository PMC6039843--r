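#' Jacobian modulation
#'
#' Voxel-wise multiplication of a warped tissue map by the Jacobian
#' determinant of the deformation, converting tissue density into a
#' volume-preserving quantity before smoothing.
#'
#' @param map tissue [volume()].
#' @param jacobian Jacobian determinant [volume()], strictly positive.
#' @return modulated [volume()].
#' @export
modulate <- function(map, jacobian) {
  check_same_grid(map, jacobian)
  j <- vol_data(jacobian)
  n_bad <- sum(j <= 0)
  if (n_bad > 0L)
    stop("jacobian has ", n_bad, " non-positive voxel(s)")
  volume_like(vol_data(map) * j, map)
}

# design matrix for the two-group voxel-wise GLM:
# [group indicator (preVaD = 1), covariates..., intercept]
vbm_design <- function(group, covariates = NULL, n = length(group)) {
  g <- if (is.numeric(group)) as.numeric(group == max(group))
       else as.numeric(as.character(group) == "preVaD")
  X <- cbind(group = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match subjects")
    X <- cbind(X, covariates)
  }
  X <- cbind(X, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  X
}

# batched OLS t-statistics for contrast `cvec` over Y (n x V)
fit_tstats <- function(Y, X, cvec) {
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cb <- drop(crossprod(cvec, B))
  cXXc <- drop(t(cvec) %*% XtXi %*% cvec)
  se <- sqrt(pmax(sigma2, 0) * cXXc)
  zero <- sigma2 <= 1e-24 | se == 0
  tt <- numeric(length(se))
  tt[!zero] <- cb[!zero] / se[!zero]   # zero-residual-variance voxels get t = 0
  list(t = tt, df = df, zero = zero)
}

#' Voxel-wise two-group contrast with covariate adjustment
#'
#' Fits, independently at every in-mask voxel, an OLS model of the feature
#' value on a preVaD group indicator, the covariates and an intercept, and
#' returns the contrast t-map with one-sided parametric p-values. The
#' default contrast tests the group coefficient in the positive direction;
#' negate it for the deficit direction. Voxels with zero residual variance
#' get t = 0 and are flagged.
#'
#' @param features a [extract_features()] feature matrix.
#' @param group group labels aligned with the feature rows
#'   (`"preVaD"` / `"non-convertor"`).
#' @param covariates optional numeric matrix/data frame of per-subject
#'   covariates (e.g. age, sex, lacune volume, TIV, NART).
#' @param contrast coefficient vector over `[group, covariates, intercept]`;
#'   default `c(1, 0, ..., 0)`.
#' @return object of class `svd_glm`: `t_map`, `df`, `p_unc_map` (one-sided),
#'   `design`, `contrast`, `zero_variance` flag map.
#' @export
glm_contrast <- function(features, group, covariates = NULL, contrast = NULL) {
  Y <- features$values
  n <- nrow(Y)
  if (length(group) != n) stop("group labels must match feature rows")
  X <- vbm_design(group, covariates, n)
  if (n <= ncol(X)) stop("need more subjects than design columns")
  if (is.null(contrast)) contrast <- c(1, rep(0, ncol(X) - 1L))
  stopifnot(length(contrast) == ncol(X))
  ft <- fit_tstats(Y, X, contrast)
  p_unc <- stats::pt(ft$t, df = ft$df, lower.tail = FALSE)
  structure(list(
    t_map = features_to_volume(features, ft$t),
    df = ft$df,
    p_unc_map = features_to_volume(features, p_unc, fill = 1),
    design = X, contrast = contrast,
    zero_variance = features_to_volume(features, as.numeric(ft$zero)),
    features = features, group = group
  ), class = "svd_glm")
}

#' @export
print.svd_glm <- function(x, ...) {
  tv <- vol_data(x$t_map)[x$features$voxel_idx]
  cat(sprintf("<svd_glm> %d voxels, df = %d, max |t| = %.3f\n",
              length(tv), x$df, max(abs(tv))))
  invisible(x)
}

#' Max-statistic permutation FWE correction (Freedman-Lane)
#'
#' Family-wise-error-corrected p-values for a voxel-wise group contrast by
#' permutation of the maximum statistic. Data are residualized against the
#' nuisance part of the design (covariates + intercept), the residuals are
#' permuted and added back to the nuisance fit (Freedman-Lane), the full
#' model is refitted, and the maximum t over non-degenerate voxels forms
#' the null distribution. `p_fwe(v) = (1 + #\{max-t* >= t(v)\}) /
#' (1 + n_permutations)`, so no p-value can fall below
#' `1 / (1 + n_permutations)`.
#'
#' @inheritParams glm_contrast
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param alpha nominal level used only for the resolution warning.
#' @return object of class `svd_fwe`: `p_fwe_map`, observed `t_map`,
#'   `max_t_null` (the permutation distribution), `n_permutations`.
#' @export
fwe_correct <- function(features, group, covariates = NULL, contrast = NULL,
                        n_permutations = 1000L, seed = 1L, alpha = 0.05) {
  if (n_permutations < 100L)
    stop("fwe_correct needs >= 100 permutations")
  if (1 / (1 + n_permutations) > alpha)
    warning("too few permutations to resolve alpha = ", alpha)
  Y <- features$values
  n <- nrow(Y)
  X <- vbm_design(group, covariates, n)
  if (is.null(contrast)) contrast <- c(1, rep(0, ncol(X) - 1L))
  ft_obs <- fit_tstats(Y, X, contrast)
  keep <- !ft_obs$zero
  # nuisance model: all columns the contrast does not touch
  nuis <- which(contrast == 0)
  X0 <- X[, nuis, drop = FALSE]
  H0 <- X0 %*% chol2inv(chol(crossprod(X0))) %*% t(X0)
  fitted0 <- H0 %*% Y
  resid0 <- Y - fitted0
  set.seed(seed)
  max_t <- vapply(seq_len(n_permutations), function(b) {
    pi_b <- sample.int(n)
    Yb <- fitted0 + resid0[pi_b, , drop = FALSE]
    ftb <- fit_tstats(Yb, X, contrast)
    if (any(keep & !ftb$zero)) max(ftb$t[keep & !ftb$zero]) else -Inf
  }, numeric(1))
  counts <- vapply(ft_obs$t, function(tv) sum(max_t >= tv), numeric(1))
  p_fwe <- (1 + counts) / (1 + n_permutations)
  p_fwe[!keep] <- 1
  structure(list(
    p_fwe_map = features_to_volume(features, p_fwe, fill = 1),
    t_map = features_to_volume(features, ft_obs$t),
    df = ft_obs$df,
    max_t_null = max_t,
    n_permutations = n_permutations,
    features = features
  ), class = "svd_fwe")
}

# 26-connectivity connected components of a logical 3-D array
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx_all <- which(mask)
  nb_off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb_off <- nb_off[rowSums(abs(nb_off)) > 0, , drop = FALSE]
  nextlab <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- arrayInd(cur, d)
      cand <- sweep(nb_off, 2L, as.integer(p), `+`)
      ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
        cand[, 2] >= 1L & cand[, 2] <= d[2] &
        cand[, 3] >= 1L & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nextlab
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Supra-threshold cluster table
#'
#' Labels 26-connected clusters of voxels surviving a p-map threshold and
#' tabulates cluster size, peak t and peak coordinate -- the dual-threshold
#' display convention (uncorrected p < 0.001 alongside FWE p < 0.05).
#'
#' @param t_map t [volume()].
#' @param p_map matching p [volume()] (uncorrected or FWE).
#' @param p_threshold inclusion threshold on `p_map`.
#' @return data frame: `cluster`, `n_voxels`, `volume_mm3`, `peak_t`,
#'   `peak_x`, `peak_y`, `peak_z` (0-based voxel indices), ordered by size.
#' @export
cluster_table <- function(t_map, p_map, p_threshold = 0.05) {
  check_same_grid(t_map, p_map)
  mask <- vol_data(p_map) < p_threshold
  mask[is.na(mask)] <- FALSE
  if (!any(mask))
    return(data.frame(cluster = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), peak_t = numeric(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0)))
  lab <- label_components(mask)
  tv <- vol_data(t_map)
  vv <- voxel_volume_mm3(t_map)
  rows <- lapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l)
    pk <- idx[which.max(tv[idx])]
    pc <- arrayInd(pk, dim(tv)) - 1L   # 0-based voxel indexing
    data.frame(cluster = l, n_voxels = length(idx),
               volume_mm3 = length(idx) * vv, peak_t = tv[pk],
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full baseline VBM contrast for one tissue class
#'
#' Convenience wrapper running the standard baseline voxel-wise pipeline on
#' per-subject maps: Jacobian modulation (optional), Gaussian smoothing,
#' mean-tissue analysis masking, the covariate-adjusted group GLM, and
#' max-statistic permutation FWE correction, returning both cluster tables.
#'
#' @param maps named list of per-subject tissue [volume()]s.
#' @param group aligned group labels.
#' @param jacobians optional named list of per-subject Jacobian volumes.
#' @param covariates optional covariate matrix.
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm).
#' @param mask_threshold mean-tissue mask threshold.
#' @param direction `"greater"` tests preVaD > non-convertor, `"less"` the
#'   deficit direction.
#' @param n_permutations,seed permutation settings.
#' @return list: `glm`, `fwe`, `clusters_unc` (p < 0.001 uncorrected),
#'   `clusters_fwe` (FWE p < 0.05).
#' @export
vbm_contrast <- function(maps, group, jacobians = NULL, covariates = NULL,
                         fwhm_mm = 6, mask_threshold = 0.1,
                         direction = c("greater", "less"),
                         n_permutations = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  if (!is.null(jacobians))
    maps <- Map(modulate, maps, jacobians)
  maps <- lapply(maps, gaussian_smooth, fwhm_mm = fwhm_mm)
  mask <- mean_tissue_mask(maps, mask_threshold)
  features <- extract_features(maps, mask)
  X <- vbm_design(group, covariates, length(group))
  cvec <- c(if (direction == "greater") 1 else -1, rep(0, ncol(X) - 1L))
  g <- glm_contrast(features, group, covariates, contrast = cvec)
  f <- fwe_correct(features, group, covariates, contrast = cvec,
                   n_permutations = n_permutations, seed = seed)
  list(glm = g, fwe = f,
       clusters_unc = cluster_table(g$t_map, g$p_unc_map, 0.001),
       clusters_fwe = cluster_table(f$t_map, f$p_fwe_map, 0.05))
}
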