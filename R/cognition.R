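#' Cognitive domain index
#'
#' Arithmetic mean of the available component z-scores within a cognitive
#' domain (executive function, processing speed, working memory, long-term
#' memory, or the global score over all administered tests). Missing
#' components are excluded; the number excluded is attached as an
#' attribute. All components missing is an error.
#'
#' @param components numeric vector of component z-scores (may contain
#'   `NA`).
#' @return index z-score with attribute `n_missing`.
#' @export
domain_index <- function(components) {
  stopifnot(is.numeric(components), length(components) >= 1L)
  ok <- !is.na(components)
  if (!any(ok)) stop("all component scores missing")
  structure(mean(components[ok]), n_missing = sum(!ok))
}

#' Per-subject cognitive slopes from a linear mixed-effect model
#'
#' Two-level model of domain score on time with random intercept and random
#' slope per subject (unstructured 2x2 random-effect covariance), fitted by
#' maximum likelihood; the per-subject empirical-best-linear-unbiased slope
#' (fixed slope + random deviation) is extracted. A per-subject OLS slope
#' is always computed alongside; on LME non-convergence the OLS slopes are
#' returned with `method = "per-subject-OLS"` and a warning. LME slopes
#' exhibit shrinkage toward the fixed effect, so their variance never
#' exceeds the OLS slope variance.
#'
#' @param scores numeric domain scores, one per visit row.
#' @param times visit times in years, aligned with `scores`.
#' @param subjects subject ids aligned with `scores`.
#' @return object of class `svd_slopes`: `slope` (named per-subject),
#'   `ols_slope`, `fixed_slope`, `method` tag.
#' @export
fit_random_slopes <- function(scores, times, subjects) {
  stopifnot(length(scores) == length(times), length(times) == length(subjects))
  keep <- !is.na(scores)
  d <- data.frame(y = scores[keep], t = times[keep],
                  id = as.character(subjects[keep]))
  n_visits <- table(d$id)
  if (mean(n_visits >= 2L) < 0.5)
    stop("need >= 2 visits for at least half the subjects")
  ids <- sort(unique(d$id))
  ols <- vapply(ids, function(s) {
    di <- d[d$id == s, ]
    if (nrow(di) < 2L || length(unique(di$t)) < 2L) return(NA_real_)
    annualized_rate(di$y, di$t)
  }, numeric(1))
  lme_slopes <- NULL; fixed <- NA_real_; method <- "LME-random-slope"
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ t + (1 + t | id), data = d, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fixed <- lme4::fixef(fit)[["t"]]
    re <- lme4::ranef(fit)$id
    lme_slopes <- stats::setNames(fixed + re[ids, "t"], ids)
  }
  if (is.null(lme_slopes)) {
    warning("LME did not converge; per-subject OLS slopes returned")
    method <- "per-subject-OLS"
    lme_slopes <- ols
  }
  structure(list(slope = lme_slopes, ols_slope = ols,
                 fixed_slope = fixed, method = method),
            class = "svd_slopes")
}

#' @export
print.svd_slopes <- function(x, ...) {
  cat(sprintf("<svd_slopes> %d subjects, %s, mean slope %.4g z/y\n",
              length(x$slope), x$method, mean(x$slope, na.rm = TRUE)))
  invisible(x)
}

#' Baseline two-group comparison table
#'
#' Per-variable comparison between preVaD and non-convertors: a two-sample
#' t-test for continuous variables, Kruskal-Wallis for variables flagged as
#' ordinal/bounded (MMSE, Rankin by default), with Bonferroni correction
#' over the tested family (the corrected level is `0.05 / n_variables`).
#' Constant variables are skipped with a note.
#'
#' @param data data frame of per-subject variables.
#' @param group two-level group factor aligned with rows.
#' @param nonparametric character vector of variable names tested with
#'   Kruskal-Wallis instead of the t-test.
#' @param family_alpha family-wise level before correction.
#' @return data frame: variable, per-group mean (SD), test used, raw p,
#'   Bonferroni threshold, significance flag.
#' @export
baseline_comparison <- function(data, group,
                                nonparametric = c("mmse", "rankin"),
                                family_alpha = 0.05) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, nrow(data) == length(group))
  vars <- names(data)[vapply(data, is.numeric, logical(1))]
  thr <- family_alpha / length(vars)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    g1 <- x[group == levels(group)[1L]]
    g2 <- x[group == levels(group)[2L]]
    row <- data.frame(variable = v,
                      mean_1 = mean(g1, na.rm = TRUE),
                      sd_1 = stats::sd(g1, na.rm = TRUE),
                      mean_2 = mean(g2, na.rm = TRUE),
                      sd_2 = stats::sd(g2, na.rm = TRUE))
    if (isTRUE(stats::var(x, na.rm = TRUE) == 0) ||
        all(is.na(g1)) || all(is.na(g2))) {
      row$test <- "skipped (constant)"
      row$p <- NA_real_
    } else if (v %in% nonparametric) {
      row$test <- "kruskal-wallis"
      row$p <- stats::kruskal.test(x, group)$p.value
    } else {
      row$test <- "t-test"
      row$p <- stats::t.test(g1, g2)$p.value
    }
    row
  })
  out <- do.call(rbind, rows)
  out$bonferroni_threshold <- thr
  out$significant <- !is.na(out$p) & out$p < thr
  names(out)[2:5] <- paste0(rep(c("mean_", "sd_"), 2),
                            rep(levels(group), each = 2))
  rownames(out) <- NULL
  out
}
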