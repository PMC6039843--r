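#' Threshold selection for a risk marker
#'
#' Sensitivity and specificity of the rule "predict positive iff
#' marker >= threshold" over a threshold grid, with the operating point
#' selected by Youden's J (`sens + spec - 1`; ties resolved to the smallest
#' threshold). Used to pick the vascular-burden (SVDp) cutoff separating
#' high- from low-burden subjects.
#'
#' @param marker numeric marker values (upward-risky).
#' @param outcome logical/0-1 outcome; both classes must be present.
#' @param grid threshold grid; defaults to the sorted unique marker values.
#' @return object of class `svd_threshold`: `table` (threshold, sensitivity,
#'   specificity, youden_j), `selected` threshold, `selected_j`.
#' @export
threshold_select <- function(marker, outcome, grid = NULL) {
  outcome <- as.logical(outcome)
  stopifnot(length(marker) == length(outcome))
  if (!any(outcome) || all(outcome))
    stop("both outcome classes must be present")
  if (diff(range(marker)) == 0) stop("degenerate (constant) marker")
  if (is.null(grid)) grid <- sort(unique(marker))
  tab <- do.call(rbind, lapply(grid, function(th) {
    pred <- marker >= th
    data.frame(threshold = th,
               sensitivity = 100 * mean(pred[outcome]),
               specificity = 100 * mean(!pred[!outcome]))
  }))
  tab$youden_j <- (tab$sensitivity + tab$specificity) / 100 - 1
  best <- which(tab$youden_j == max(tab$youden_j))
  sel <- tab$threshold[min(best)]   # ties: smallest threshold
  structure(list(table = tab, selected = sel,
                 selected_j = max(tab$youden_j)),
            class = "svd_threshold")
}

#' @export
print.svd_threshold <- function(x, ...) {
  i <- match(x$selected, x$table$threshold)
  cat(sprintf(paste0("<svd_threshold> selected %.3g (J = %.3f, ",
                     "sens %.1f%%, spec %.1f%%) over %d grid points\n"),
              x$selected, x$selected_j, x$table$sensitivity[i],
              x$table$specificity[i], nrow(x$table)))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the conversion-free survival function;
#' censored subjects leave the risk set at their time without an event
#' step. The median is the smallest event time with survival <= 0.5,
#' undefined (`NA`) when the curve never reaches 0.5.
#'
#' @param event_times observed times in years (> 0).
#' @param event_flags logical; `TRUE` = conversion observed, `FALSE` =
#'   censored.
#' @return object of class `svd_km`: `time`, `survival`, `at_risk`,
#'   `events` per time, `median`, `n`, plus the underlying
#'   `survival::survfit` object.
#' @export
kaplan_meier <- function(event_times, event_flags) {
  stopifnot(length(event_times) == length(event_flags))
  if (any(event_times < 0)) stop("negative event times")
  fit <- survival::survfit(
    survival::Surv(event_times, as.numeric(event_flags)) ~ 1,
    conf.type = "none")
  med <- {
    i <- which(fit$surv <= 0.5 & fit$n.event > 0)
    if (length(i)) fit$time[min(i)] else NA_real_
  }
  structure(list(time = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, events = fit$n.event,
                 median = med, n = length(event_times), survfit = fit),
            class = "svd_km")
}

#' @export
print.svd_km <- function(x, ...) {
  cat(sprintf("<svd_km> n = %d, %d events, median %s y\n",
              x$n, sum(x$events),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Survival probability at a time
#'
#' Step-function evaluation of a [kaplan_meier()] curve; `S(t) = 1` before
#' the first event.
#'
#' @param km a `svd_km`.
#' @param t time in years.
#' @return survival probability.
#' @export
km_survival_at <- function(km, t) {
  i <- which(km$time <= t)
  if (!length(i)) 1 else km$survival[max(i)]
}

#' Log-rank test
#'
#' Standard log-rank statistic (observed minus expected events under the
#' hypergeometric distribution at each event time), chi-square with
#' `groups - 1` degrees of freedom.
#'
#' @param event_times,event_flags as in [kaplan_meier()].
#' @param groups group labels (>= 2 non-empty groups, >= 1 event overall).
#' @return list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(event_times, event_flags, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 non-empty groups")
  if (!any(as.logical(event_flags))) stop("need >= 1 event")
  sd_fit <- survival::survdiff(
    survival::Surv(event_times, as.numeric(event_flags)) ~ groups)
  df <- length(sd_fit$n) - 1L
  list(chisq = sd_fit$chisq, df = df,
       p = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
}

#' Prediction x vascular-burden stratified survival analysis
#'
#' Splits the cohort into four strata -- SVM prediction (positive/negative)
#' crossed with vascular burden (SVDp at or above vs below the threshold) --
#' and reports the per-stratum Kaplan-Meier curve and 5-year conversion
#' probability `1 - S(5)`, plus the log-rank test between the two SVM
#' prediction groups. Empty strata are reported as missing rows, not
#' errors; a threshold at the marker maximum leaves a single populated
#' burden level and triggers a warning.
#'
#' @param prediction_positive logical per-subject SVM prediction.
#' @param svdp_values per-subject SVDp percentages.
#' @param threshold vascular-burden cutoff (percent), within the marker
#'   range.
#' @param event_times,event_flags conversion outcome per subject.
#' @param at_years horizon for the conversion-probability column.
#' @return object of class `svd_strata`: `strata` table (stratum, n,
#'   events, conversion probability), `curves` (named list of `svd_km` or
#'   `NULL`), `logrank` between prediction groups.
#' @export
stratified_analysis <- function(prediction_positive, svdp_values, threshold,
                                event_times, event_flags, at_years = 5) {
  n <- length(event_times)
  stopifnot(length(prediction_positive) == n, length(svdp_values) == n,
            length(event_flags) == n)
  if (threshold < min(svdp_values) || threshold > max(svdp_values))
    stop("threshold outside the marker range")
  high <- svdp_values >= threshold
  if (all(high) || !any(high) || threshold >= max(svdp_values))
    warning("threshold leaves a single populated burden stratum")
  stratum <- interaction(ifelse(prediction_positive, "positive", "negative"),
                         ifelse(high, "high", "low"), sep = "/")
  levs <- c("positive/high", "positive/low", "negative/high", "negative/low")
  curves <- stats::setNames(vector("list", length(levs)), levs)
  rows <- lapply(levs, function(lv) {
    idx <- which(as.character(stratum) == lv)
    if (!length(idx))
      return(data.frame(stratum = lv, n = 0L, events = 0L,
                        conversion_prob = NA_real_))
    km <- kaplan_meier(event_times[idx], event_flags[idx])
    curves[[lv]] <<- km
    data.frame(stratum = lv, n = length(idx),
               events = sum(as.logical(event_flags[idx])),
               conversion_prob = 1 - km_survival_at(km, at_years))
  })
  lr <- logrank_test(event_times, event_flags,
                     ifelse(prediction_positive, "positive", "negative"))
  structure(list(strata = do.call(rbind, rows), curves = curves,
                 logrank = lr, threshold = threshold, at_years = at_years),
            class = "svd_strata")
}

#' @export
print.svd_strata <- function(x, ...) {
  cat(sprintf("<svd_strata> SVDp threshold %.3g%%, log-rank p = %.4g\n",
              x$threshold, x$logrank$p))
  print(x$strata)
  invisible(x)
}
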