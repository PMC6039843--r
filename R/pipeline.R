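#' Pipeline configuration
#'
#' Returns the default configuration for the command-line pipeline, or the
#' defaults overridden by the keys of a YAML file. Documented keys:
#' `grid_shape`, `voxel_size_mm`, `n_per_group`, `gm_reduction_fraction`,
#' `wmh_excess`, `noise_sd`, `n_timepoints`, `dropout_prob`, `horizon`
#' (generator); `fwhm_mm`, `mask_threshold`, `n_permutations` (voxel-wise
#' stats); `svm_cost`, `roi_sets` (prediction); `k_subtypes` (clustering);
#' `svdp_threshold` (survival; `NULL` selects by Youden's J);
#' `wmh_threshold`, `tissue_threshold` (volumetrics).
#'
#' @param path optional YAML file whose keys override the defaults.
#' @return named list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(
    grid_shape = c(32L, 32L, 32L), voxel_size_mm = 2,
    n_per_group = c("non-convertor" = 97L, "preVaD" = 22L),
    gm_reduction_fraction = 0.15, wmh_excess = 0.2, noise_sd = 0.05,
    n_timepoints = 4L, dropout_prob = 0.1, horizon = 5,
    fwhm_mm = 6, mask_threshold = 0.1, n_permutations = 500L,
    svm_cost = 1, roi_sets = c("striatum + hippocampus"),
    k_subtypes = 4L, svdp_threshold = NULL,
    wmh_threshold = 0.5, tissue_threshold = 0.2)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
    if (is.null(names(cfg$n_per_group)))
      names(cfg$n_per_group) <- c("non-convertor", "preVaD")
  }
  cfg
}

config_effects <- function(cfg) {
  np <- cfg$n_per_group
  if (is.null(names(np))) names(np) <- c("non-convertor", "preVaD")
  effect_spec(n_per_group = np,
              gm_reduction_fraction = cfg$gm_reduction_fraction,
              wmh_excess = cfg$wmh_excess, noise_sd = cfg$noise_sd,
              n_timepoints = cfg$n_timepoints,
              dropout_prob = cfg$dropout_prob, horizon = cfg$horizon,
              grid_shape = cfg$grid_shape,
              voxel_size_mm = cfg$voxel_size_mm)
}

#' Simulate a cohort and write it to a run directory
#'
#' Writes per-subject NIfTI volumes (tissues, lacunes, Jacobian, divergence
#' series), the cohort and visit CSVs, and a ground-truth JSON of planted
#' parameters for harnesses.
#'
#' @param config a [pipeline_config()] list.
#' @param seed integer seed.
#' @param out output directory (created if needed).
#' @return `out`, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), seed = 1L, out) {
  sim <- simulate_cohort(config_effects(config), seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_cohort(sim$cohort, file.path(out, "cohort.csv"),
               file.path(out, "visits.csv"))
  for (s in sim$subjects) {
    sd <- file.path(out, "subjects", s$id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    for (k in names(s$tissues))
      write_volume(s$tissues[[k]], file.path(sd, paste0(k, ".nii.gz")))
    write_volume(s$jacobian, file.path(sd, "jacobian.nii.gz"))
    for (i in seq_along(s$divergence$times))
      write_volume(s$divergence$maps[[i]],
                   file.path(sd, sprintf("divergence_t%02d.nii.gz", i)))
    writeLines(paste(s$divergence$times, collapse = ","),
               file.path(sd, "divergence_times.txt"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- sim$truth
    jsonlite::write_json(
      list(seed = tr$seed, subtype = as.list(tr$subtype),
           group = as.list(tr$group),
           gm_reduction_fraction = tr$effects$gm_reduction_fraction,
           wmh_excess = tr$effects$wmh_excess,
           noise_sd = tr$effects$noise_sd),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Load a simulated run directory
#'
#' Reads back what [run_simulate()] wrote: the cohort, per-subject volumes
#' and divergence series.
#'
#' @param dir run directory.
#' @return list with `cohort` and `subjects` (as in [simulate_cohort()]).
#' @export
load_run <- function(dir) {
  cohort <- load_cohort(file.path(dir, "cohort.csv"),
                        file.path(dir, "visits.csv"))
  ids <- cohort$subjects$id
  subjects <- lapply(ids, function(id) {
    sd <- file.path(dir, "subjects", id)
    tis <- lapply(c(gm = "gm", wm = "wm", csf = "csf", wmh = "wmh",
                    lacunes = "lacunes"),
                  function(k) read_volume(file.path(sd, paste0(k, ".nii.gz"))))
    times <- as.numeric(strsplit(readLines(
      file.path(sd, "divergence_times.txt"))[1], ",")[[1]])
    maps <- lapply(seq_along(times), function(i)
      read_volume(file.path(sd, sprintf("divergence_t%02d.nii.gz", i))))
    structure(list(id = id, tissues = tis,
                   jacobian = read_volume(file.path(sd, "jacobian.nii.gz")),
                   divergence = list(times = times, maps = maps),
                   scan_times = times),
              class = "svd_subject")
  })
  names(subjects) <- ids
  list(cohort = cohort, subjects = subjects)
}

# confound matrix used by the VBM and prediction stages
standard_confounds <- function(cohort, volumetrics = NULL) {
  s <- cohort$subjects
  cf <- cbind(age = s$age, male = as.numeric(s$sex == "male"),
              tiv = s$tiv_mm3, nart = s$nart)
  if (!is.null(volumetrics))
    cf <- cbind(cf, lacune = volumetrics$lacune_mm3[match(s$id, volumetrics$id)])
  cf
}

#' Run the volumetry stage on a run directory
#'
#' @param dir run directory from [run_simulate()].
#' @param config a [pipeline_config()] list.
#' @param out output CSV path.
#' @return the volumetric table, invisibly.
#' @export
run_volumetry <- function(dir, config = pipeline_config(), out) {
  run <- load_run(dir)
  vt <- volumetrics_table(run$subjects, run$cohort,
                          threshold = config$tissue_threshold,
                          wmh_threshold = config$wmh_threshold)
  utils::write.csv(vt, out, row.names = FALSE)
  invisible(vt)
}

#' Run the lacune-analysis stage
#'
#' Writes the per-group overlap maps, their difference, and the ROI
#' incidence table.
#'
#' @inheritParams run_volumetry
#' @param out output directory.
#' @return the incidence table, invisibly.
#' @export
run_lesions <- function(dir, config = pipeline_config(), out) {
  run <- load_run(dir)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  atlas <- make_atlas(config$grid_shape, config$voxel_size_mm)
  masks <- lapply(run$subjects, function(s) s$tissues$lacunes)
  grp <- as.character(run$cohort$subjects$group)
  for (g in unique(grp))
    write_volume(overlap_map(masks[grp == g]),
                 file.path(out, paste0("overlap_", gsub("[^a-zA-Z]", "_", g),
                                       ".nii.gz")))
  inc <- roi_incidence(masks, atlas, grp)
  utils::write.csv(inc, file.path(out, "incidence.csv"), row.names = FALSE)
  utils::write.csv(attr(inc, "asymmetry"),
                   file.path(out, "asymmetry.csv"), row.names = FALSE)
  invisible(inc)
}

#' Run the baseline voxel-wise (VBM) stage
#'
#' Modulated, smoothed GM deficit contrast (preVaD < non-convertor) and WMH
#' excess contrast with the standard covariates; writes t-maps, p-maps and
#' cluster tables.
#'
#' @inheritParams run_lesions
#' @param seed permutation seed.
#' @return list of the two contrasts, invisibly.
#' @export
run_vbm <- function(dir, config = pipeline_config(), seed = 1L, out) {
  run <- load_run(dir)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grp <- as.character(run$cohort$subjects$group)
  vt <- volumetrics_table(run$subjects, run$cohort)
  cf <- standard_confounds(run$cohort, vt)
  res <- list(
    gm_deficit = vbm_contrast(
      lapply(run$subjects, function(s) s$tissues$gm), grp,
      jacobians = lapply(run$subjects, function(s) s$jacobian),
      covariates = cf, fwhm_mm = config$fwhm_mm,
      mask_threshold = config$mask_threshold, direction = "less",
      n_permutations = config$n_permutations, seed = seed),
    wmh_excess = vbm_contrast(
      lapply(run$subjects, function(s) s$tissues$wmh), grp,
      covariates = cf, fwhm_mm = config$fwhm_mm,
      mask_threshold = config$mask_threshold / 2, direction = "greater",
      n_permutations = config$n_permutations, seed = seed))
  for (nm in names(res)) {
    write_volume(res[[nm]]$glm$t_map, file.path(out, paste0(nm, "_t.nii.gz")))
    write_volume(res[[nm]]$fwe$p_fwe_map,
                 file.path(out, paste0(nm, "_pfwe.nii.gz")))
    utils::write.csv(res[[nm]]$clusters_fwe,
                     file.path(out, paste0(nm, "_clusters_fwe.csv")),
                     row.names = FALSE)
    utils::write.csv(res[[nm]]$clusters_unc,
                     file.path(out, paste0(nm, "_clusters_p001.csv")),
                     row.names = FALSE)
  }
  invisible(res)
}

#' Run the longitudinal rate-map stage
#'
#' Per-subject voxel-wise rate maps from the divergence series, GM-weighted
#' WWA-smoothed rate maps, and the hippocampal ROI rate table.
#'
#' @inheritParams run_lesions
#' @return the ROI-rate table, invisibly.
#' @export
run_rates <- function(dir, config = pipeline_config(), out) {
  run <- load_run(dir)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  atlas <- make_atlas(config$grid_shape, config$voxel_size_mm)
  hip <- roi_mask(atlas, "hippocampus")
  rows <- lapply(run$subjects, function(s) {
    rm <- fit_voxel_rates(s$divergence)
    write_volume(rm$slope, file.path(out, paste0(s$id, "_rate.nii.gz")))
    data.frame(id = s$id, n_timepoints = rm$n_timepoints,
               hippocampal_rate = roi_mean_rate(rm, hip))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out, "roi_rates.csv"), row.names = FALSE)
  invisible(tab)
}

#' Run the SVM prediction stage
#'
#' ROI-masked leave-one-out prediction on the Jacobian maps with the
#' standard confounds; writes the metric table and the per-subject
#' decision values consumed by the survival stage.
#'
#' @inheritParams run_vbm
#' @return the prediction table, invisibly.
#' @export
run_predict <- function(dir, config = pipeline_config(), seed = 1L, out) {
  run <- load_run(dir)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  atlas <- make_atlas(config$grid_shape, config$voxel_size_mm)
  grp <- as.character(run$cohort$subjects$group)
  cf <- standard_confounds(run$cohort)
  jac <- lapply(run$subjects, function(s) s$jacobian)
  tab <- roi_prediction_table(jac, grp, cf, roi_sets = config$roi_sets,
                              atlas = atlas, C = config$svm_cost,
                              n_permutations = 0L, seed = seed)
  utils::write.csv(tab, file.path(out, "prediction_table.csv"),
                   row.names = FALSE)
  best <- config$roi_sets[[1L]]
  res <- loo_predict(extract_features(jac, roi_mask(atlas, best)), grp, cf,
                     C = config$svm_cost)
  utils::write.csv(
    data.frame(id = run$cohort$subjects$id,
               decision_value = res$decision_values,
               predicted = res$predicted),
    file.path(out, "decisions.csv"), row.names = FALSE)
  invisible(tab)
}

#' Run the anatomical-subtyping stage
#'
#' Ward-linkage clustering of the convertors' in-brain Jacobian vectors;
#' writes the linkage table, subtype labels and subgroup summary.
#'
#' @inheritParams run_lesions
#' @return the subtype labels, invisibly.
#' @export
run_cluster <- function(dir, config = pipeline_config(), out) {
  run <- load_run(dir)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  conv <- run$cohort$subjects$id[run$cohort$subjects$converted]
  brain <- make_brain_mask(config$grid_shape, config$voxel_size_mm)
  feats <- extract_features(
    lapply(run$subjects[conv], function(s) s$jacobian), brain)
  tree <- ward_linkage(subject_similarity(feats))
  labels <- cut_tree(tree, config$k_subtypes)
  vt <- volumetrics_table(run$subjects, run$cohort)
  summ <- subgroup_summary(labels, run$cohort, vt)
  utils::write.csv(tree$merges, file.path(out, "linkage.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = names(labels), subtype = labels),
                   file.path(out, "labels.csv"), row.names = FALSE)
  utils::write.csv(summ, file.path(out, "subgroup_summary.csv"),
                   row.names = FALSE)
  invisible(labels)
}

#' Run the survival stage
#'
#' Selects the SVDp threshold (Youden's J unless fixed in the config),
#' builds the prediction x burden strata, and writes the curves and
#' log-rank results.
#'
#' @inheritParams run_lesions
#' @param predict_dir directory holding `decisions.csv` from
#'   [run_predict()].
#' @return the `svd_strata` object, invisibly.
#' @export
run_survive <- function(dir, predict_dir, config = pipeline_config(), out) {
  run <- load_run(dir)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dec <- utils::read.csv(file.path(predict_dir, "decisions.csv"))
  s <- run$cohort$subjects
  dec <- dec[match(s$id, dec$id), ]
  vt <- volumetrics_table(run$subjects, run$cohort)
  sv <- vt$svdp_percent[match(s$id, vt$id)]
  thr <- config$svdp_threshold
  if (is.null(thr)) {
    ts <- threshold_select(sv, s$converted)
    thr <- ts$selected
    utils::write.csv(ts$table, file.path(out, "threshold_curve.csv"),
                     row.names = FALSE)
  }
  res <- stratified_analysis(dec$decision_value > 0, sv, thr,
                             s$event_time, s$converted)
  utils::write.csv(res$strata, file.path(out, "strata.csv"),
                   row.names = FALSE)
  for (lv in names(res$curves)) {
    km <- res$curves[[lv]]
    if (is.null(km)) next
    utils::write.csv(
      data.frame(time = km$time, survival = km$survival,
                 at_risk = km$at_risk, events = km$events),
      file.path(out, paste0("km_", gsub("/", "_", lv), ".csv")),
      row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(
      list(threshold = thr, chisq = res$logrank$chisq,
           df = res$logrank$df, p = res$logrank$p),
      file.path(out, "logrank.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
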