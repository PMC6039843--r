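#' Construct a cohort table
#'
#' Joins the imaging arm of the study to demographics, cognition and the
#' conversion outcome. A cohort is a subject-level data frame plus an
#' optional long table of per-visit cognitive domain z-scores. The group
#' factor (`preVaD` for subjects who converted to dementia within the
#' follow-up horizon, `non-convertor` otherwise) is derived from the
#' `converted` flag.
#'
#' Subject columns: `id`, `age` (years), `sex` (`male`/`female`), `nart`,
#' `rankin`, `tiv_mm3`, `mmse`, `converted` (logical), `event_time`
#' (years to dementia or censoring, > 0), `scan_times` (list column of
#' years-from-baseline, strictly increasing from 0), optional `subtype`.
#' Visit columns: `id`, `time`, then one column per cognitive domain
#' (`ef`, `ps`, `wm`, `ltm`, `global`).
#'
#' @param subjects subject-level `data.frame` as above.
#' @param visits optional per-visit cognitive `data.frame`.
#' @param horizon administrative follow-up horizon in years.
#' @return object of class `svd_cohort`.
#' @export
cohort_table <- function(subjects, visits = NULL, horizon = 5) {
  stopifnot(is.data.frame(subjects))
  req <- c("id", "age", "sex", "converted", "event_time")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  subjects$id <- as.character(subjects$id)
  dup <- subjects$id[duplicated(subjects$id)]
  if (length(dup)) stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  subjects$converted <- as.logical(subjects$converted)
  if (any(!is.finite(subjects$event_time)) || any(subjects$event_time <= 0))
    stop("event_time must be positive for every subject")
  late <- subjects$converted & subjects$event_time > horizon
  if (any(late)) {
    warning("converted subject(s) with event_time beyond the ", horizon,
            "-y horizon kept but flagged: ",
            paste(subjects$id[late], collapse = ", "))
    subjects$beyond_horizon <- late
  }
  if (!is.null(subjects$scan_times)) {
    if (!is.list(subjects$scan_times))
      subjects$scan_times <- parse_scan_times(subjects$scan_times)
    ok <- vapply(subjects$scan_times, function(st)
      length(st) >= 1L && st[1] == 0 && (length(st) == 1L || all(diff(st) > 0)),
      logical(1))
    if (any(!ok))
      stop("scan_times must be strictly increasing starting at 0; offending id(s): ",
           paste(subjects$id[!ok], collapse = ", "))
  }
  subjects$group <- factor(ifelse(subjects$converted, "preVaD", "non-convertor"),
                           levels = c("non-convertor", "preVaD"))
  if (!is.null(visits)) {
    stopifnot(is.data.frame(visits), all(c("id", "time") %in% names(visits)))
    visits$id <- as.character(visits$id)
    unknown <- setdiff(visits$id, subjects$id)
    if (length(unknown)) stop("visit rows for unknown id(s): ",
                              paste(unique(unknown), collapse = ", "))
  }
  structure(list(subjects = subjects, visits = visits, horizon = horizon),
            class = "svd_cohort")
}

parse_scan_times <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(s) as.numeric(s))
}

#' @export
print.svd_cohort <- function(x, ...) {
  n <- nrow(x$subjects)
  k <- sum(x$subjects$converted)
  cat(sprintf("<svd_cohort> %d subjects (%d preVaD, %d non-convertor), %g-y horizon\n",
              n, k, n - k, x$horizon))
  invisible(x)
}

#' Load a cohort from CSV
#'
#' Reads the documented cohort schema (see [cohort_table()]): one
#' subject-level CSV with `scan_times` encoded as a `;`-separated string,
#' and an optional per-visit cognitive CSV. All record invariants are
#' validated; violations abort with the offending subject id.
#'
#' @param path subject-level CSV.
#' @param visits_path optional per-visit cognition CSV.
#' @param horizon follow-up horizon in years.
#' @return a `svd_cohort`.
#' @export
load_cohort <- function(path, visits_path = NULL, horizon = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  subjects <- utils::read.csv(path, stringsAsFactors = FALSE)
  visits <- if (!is.null(visits_path)) utils::read.csv(visits_path, stringsAsFactors = FALSE)
  cohort_table(subjects, visits, horizon = horizon)
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()]; the `scan_times` list column is serialized
#' as a `;`-separated string.
#'
#' @param cohort a `svd_cohort`.
#' @param path subject-level CSV path.
#' @param visits_path optional per-visit CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, visits_path = NULL) {
  s <- cohort$subjects
  if (is.list(s$scan_times))
    s$scan_times <- vapply(s$scan_times, paste, character(1), collapse = ";")
  s$group <- NULL
  utils::write.csv(s, path, row.names = FALSE)
  if (!is.null(visits_path) && !is.null(cohort$visits))
    utils::write.csv(cohort$visits, visits_path, row.names = FALSE)
  invisible(path)
}
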