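#' Classification metric suite
#'
#' Assembles the full metric set from confusion counts and (optionally)
#' decision values: total and balanced accuracy, sensitivity, specificity,
#' positive and negative predictive value (all in percent) and the
#' rank-based AUC (ties get half credit). Ratios with zero denominators are
#' reported as `NA`, not 0.
#'
#' @param TP,FP,TN,FN confusion counts.
#' @param decision_values optional per-subject decision values for the AUC.
#' @param labels optional logical/“positive class” labels aligned with
#'   `decision_values` (`TRUE` = positive).
#' @return list of metrics (percent scale; `auc` in \[0, 1\]).
#' @export
classification_metrics <- function(TP, FP, TN, FN,
                                   decision_values = NULL, labels = NULL) {
  counts <- c(TP, FP, TN, FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- TP + FP + TN + FN
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- ratio(TP, TP + FN)
  spec <- ratio(TN, TN + FP)
  auc <- NA_real_
  if (!is.null(decision_values) && !is.null(labels)) {
    pos <- as.logical(labels)
    stopifnot(length(decision_values) == length(pos))
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 > 0 && n0 > 0) {
      r <- rank(decision_values, ties.method = "average")
      auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(total_accuracy = ratio(TP + TN, n),
       balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                           else (sens + spec) / 2,
       sensitivity = sens, specificity = spec,
       ppv = ratio(TP, TP + FP), npv = ratio(TN, TN + FN),
       auc = auc)
}

# residualize features against confounds using coefficients estimated on
# the training rows only (per-feature OLS with intercept)
residualize_confounds <- function(values, confounds, train_idx) {
  if (is.null(confounds)) return(values)
  Xc <- cbind(1, as.matrix(confounds))
  Xt <- Xc[train_idx, , drop = FALSE]
  beta <- chol2inv(chol(crossprod(Xt))) %*%
    crossprod(Xt, values[train_idx, , drop = FALSE])
  values - Xc %*% beta
}

# linear SVM decision value for the held-out row, oriented so that
# positive values favour the positive class
svm_decision <- function(x_train, y_train, x_test, positive, C) {
  fit <- e1071::svm(x = x_train, y = y_train, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
  pr <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1L]][1L]
  if (first == positive) dv else -dv
}

#' Leave-one-out SVM prediction of conversion
#'
#' The baseline-MRI decoding protocol: for each left-out subject, per-feature
#' confound regression coefficients and feature means are estimated on the
#' training fold only and applied to all rows (no leakage), a soft-margin
#' linear-kernel SVM (default cost 1) is trained on the fold, and the
#' held-out decision value is recorded. Labels are predicted at decision
#' threshold 0 and the metric suite is assembled from held-out predictions
#' only.
#'
#' @param features a [extract_features()] matrix or plain subjects x
#'   features matrix.
#' @param labels group labels; `positive` names the positive class.
#' @param confounds optional per-subject confound matrix (age, sex, TIV,
#'   NART), rows aligned with the features.
#' @param C soft-margin penalty (toolbox default 1).
#' @param positive positive class label.
#' @return object of class `svd_prediction`: per-subject `decision_values`
#'   and `predicted`, confusion counts, and `metrics`
#'   (see [classification_metrics()]).
#' @export
loo_predict <- function(features, labels, confounds = NULL, C = 1,
                        positive = "preVaD") {
  values <- if (inherits(features, "svd_features")) features$values else features
  values <- as.matrix(values)
  n <- nrow(values)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (!positive %in% labels) stop("positive class '", positive, "' absent")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n)
  }
  if (min(table(labels)) < 2L)
    stop("need >= 2 subjects per class for leave-one-out")
  dv <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (length(unique(labels[train])) < 2L)
      stop("a class is absent from the training fold for subject ", i)
    Z <- residualize_confounds(values, confounds, train)
    mu <- colMeans(Z[train, , drop = FALSE])
    Z <- sweep(Z, 2L, mu)
    dv[i] <- svm_decision(Z[train, , drop = FALSE],
                          factor(labels[train]),
                          Z[i, , drop = FALSE], positive, C)
  }
  if (any(!is.finite(dv))) stop("non-finite decision value(s)")
  predicted <- ifelse(dv > 0, positive, setdiff(unique(labels), positive)[1L])
  is_pos <- labels == positive
  TP <- sum(predicted == positive & is_pos)
  FP <- sum(predicted == positive & !is_pos)
  TN <- sum(predicted != positive & !is_pos)
  FN <- sum(predicted != positive & is_pos)
  structure(list(decision_values = dv, predicted = predicted,
                 labels = labels, positive = positive,
                 TP = TP, FP = FP, TN = TN, FN = FN,
                 metrics = classification_metrics(TP, FP, TN, FN, dv, is_pos)),
            class = "svd_prediction")
}

#' @export
print.svd_prediction <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<svd_prediction> n = %d: total %.2f%%, balanced %.2f%%, ",
                     "sens %.2f%%, spec %.2f%%, AUC %.3f\n"),
              length(x$labels), m$total_accuracy, m$balanced_accuracy,
              m$sensitivity, m$specificity, m$auc))
  invisible(x)
}

#' Permutation p-value for a prediction statistic
#'
#' Reruns the full leave-one-out pipeline (confound regression, centering,
#' SVM) under label permutation and reports
#' `p = (1 + #\{perm >= observed\}) / (1 + n_valid)`. Permutations on which
#' the statistic is undefined are dropped with a warning and the
#' denominator adjusted.
#'
#' @inheritParams loo_predict
#' @param statistic function mapping a `svd_prediction` to a scalar
#'   (default: balanced accuracy).
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed.
#' @return list: `p`, `observed`, `null` (permutation statistics).
#' @export
permutation_pvalue <- function(features, labels, confounds = NULL, C = 1,
                               statistic = function(r) r$metrics$balanced_accuracy,
                               n_permutations = 99L, seed = 1L,
                               positive = "preVaD") {
  if (n_permutations < 99L) stop("needs >= 99 permutations")
  obs <- statistic(loo_predict(features, labels, confounds, C, positive))
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(b) {
    lb <- sample(labels)
    tryCatch(statistic(loo_predict(features, lb, confounds, C, positive)),
             error = function(e) NA_real_)
  }, numeric(1))
  n_drop <- sum(is.na(null))
  if (n_drop > 0)
    warning(n_drop, " permutation(s) with undefined statistic dropped")
  null <- null[!is.na(null)]
  list(p = (1 + sum(null >= obs)) / (1 + length(null)),
       observed = obs, null = null)
}

#' ROI-masked prediction table
#'
#' Runs the leave-one-out SVM once per requested region set (atlas names,
#' `+`-joined unions, or `"whole_brain"` for the supplied brain mask) on one
#' map type, assembling one metric row per mask -- the shape of the masked
#' prediction summary table.
#'
#' @param volumes named list of per-subject [volume()]s (one map type).
#' @param labels,confounds,C,positive as in [loo_predict()].
#' @param roi_sets character vector of region-set names.
#' @param atlas a [make_atlas()] atlas.
#' @param brain_mask binary volume used for `"whole_brain"` rows.
#' @param n_permutations if > 0, adds a balanced-accuracy permutation
#'   p-value column.
#' @param seed seed for the permutation stream.
#' @return data frame, one row per region set.
#' @export
roi_prediction_table <- function(volumes, labels, confounds = NULL,
                                 roi_sets = character(0), atlas = NULL,
                                 brain_mask = NULL, C = 1,
                                 positive = "preVaD",
                                 n_permutations = 0L, seed = 1L) {
  if (length(roi_sets) == 0L)
    return(data.frame(roi = character(0), n_voxels = integer(0),
                      total_accuracy = numeric(0),
                      balanced_accuracy = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      ppv = numeric(0), npv = numeric(0), auc = numeric(0)))
  rows <- lapply(roi_sets, function(nm) {
    mask <- if (nm == "whole_brain") {
      if (is.null(brain_mask)) stop("whole_brain row needs a brain_mask")
      brain_mask
    } else {
      if (is.null(atlas)) stop("ROI row '", nm, "' needs an atlas")
      roi_mask(atlas, nm)
    }
    feats <- extract_features(volumes, mask)
    res <- loo_predict(feats, labels, confounds, C, positive)
    row <- data.frame(roi = nm, n_voxels = ncol(feats$values),
                      res$metrics, stringsAsFactors = FALSE)
    if (n_permutations > 0L) {
      row$p_balanced <- permutation_pvalue(
        feats, labels, confounds, C,
        n_permutations = n_permutations, seed = seed,
        positive = positive)$p
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
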