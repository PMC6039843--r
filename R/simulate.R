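#' Effect specification for the synthetic cohort generator
#'
#' Collects every planted parameter of the synthetic SVD cohort: the
#' convertor grey-matter deficit, white-matter-hyperintensity excess, lacune
#' placement rates, the four anatomical subtype profiles spanning a
#' vascular-extreme to Alzheimer's-like gradient, per-subtype conversion
#' hazards, noise scales, group sizes and the longitudinal visit schedule.
#' Defaults encode the study conditions the pipeline is designed around:
#' a 97/22 non-convertor/convertor split, a 15 percent GM reduction in the
#' left striatum and left hippocampus of convertors, +0.2 WMH probability in
#' frontal white matter, four annual visits, and administrative censoring at
#' five years.
#'
#' @param n_per_group named integer vector, planted group sizes
#'   (`non-convertor`, `preVaD`).
#' @param gm_reduction_fraction fractional GM loss in convertor target ROIs.
#' @param gm_rois regions receiving the convertor GM deficit.
#' @param wmh_excess additive WMH probability in convertor `wmh_rois`.
#' @param wmh_rois regions receiving the convertor WMH excess.
#' @param lacune_rate list of two named numeric vectors (`"non-convertor"`,
#'   `"preVaD"`): expected lacune count per atlas region per subject.
#' @param subtype_profiles data frame of four subtype parameter rows, see
#'   [default_subtype_profiles()].
#' @param hazard_nonconvertor conversion hazard (events/year) for planted
#'   non-convertors; 0 means they never convert.
#' @param noise_sd voxel noise SD on tissue probability maps; the Jacobian
#'   and divergence noise SDs are `noise_sd / 2` and `noise_sd / 5`.
#' @param n_timepoints number of annual imaging visits (years 0, 1, ...).
#' @param dropout_prob per-visit dropout probability after baseline.
#' @param horizon administrative censoring horizon in years.
#' @param grid_shape,voxel_size_mm template grid geometry.
#' @param quantize_conversion if `TRUE`, observed conversion times are moved
#'   to the mid-point between the bracketing annual visits (the convention
#'   for dating conversion between assessments).
#' @return object of class `svd_effects`.
#' @export
effect_spec <- function(n_per_group = c("non-convertor" = 97L, "preVaD" = 22L),
                        gm_reduction_fraction = 0.15,
                        gm_rois = c("striatum_L", "hippocampus_L"),
                        wmh_excess = 0.2,
                        wmh_rois = "frontal_wm",
                        lacune_rate = default_lacune_rates(),
                        subtype_profiles = default_subtype_profiles(),
                        hazard_nonconvertor = 0,
                        noise_sd = 0.05,
                        n_timepoints = 4L,
                        dropout_prob = 0.1,
                        horizon = 5,
                        grid_shape = c(32L, 32L, 32L),
                        voxel_size_mm = 2,
                        quantize_conversion = FALSE) {
  stopifnot(gm_reduction_fraction >= 0, gm_reduction_fraction <= 1,
            wmh_excess >= 0, wmh_excess <= 1,
            noise_sd >= 0, dropout_prob >= 0, dropout_prob < 1,
            n_timepoints >= 1, hazard_nonconvertor >= 0,
            all(unlist(lacune_rate) >= 0),
            all(subtype_profiles$hazard > 0))
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("non-convertor", "preVaD")
  structure(as.list(environment()), class = "svd_effects")
}

#' Default per-region lacune rates
#'
#' Expected lacune counts per subject per atlas region. Convertors carry a
#' left-lateralized excess in the striatum, thalamus and centrum semiovale,
#' emulating the strategic-lacune asymmetry the analysis is designed to
#' detect; right-hemisphere rates match the non-convertor background.
#'
#' @return list of two named numeric vectors.
#' @export
default_lacune_rates <- function() {
  base <- c(putamen_L = 0.20, putamen_R = 0.20,
            caudate_L = 0.10, caudate_R = 0.10,
            thalamus_L = 0.30, thalamus_R = 0.30,
            centrum_semiovale_L = 0.20, centrum_semiovale_R = 0.20)
  conv <- base
  conv[c("putamen_L", "caudate_L", "thalamus_L", "centrum_semiovale_L")] <-
    c(0.60, 0.30, 0.60, 0.55)
  list("non-convertor" = base, "preVaD" = conv)
}

#' Default anatomical subtype profiles
#'
#' Four convertor subtype parameter sets spanning two axes: vascular burden
#' (WMH and lacune multipliers, highest in subtype 1) and atrophy
#' (hippocampal GM deficit and contraction rate, highest in subtype 4).
#' Subtype 1 is the vascular extreme, subtype 4 the Alzheimer's-like
#' extreme, 2 and 3 intermediate. Mixture weights default to 5/2/5/10 of 22.
#' Cognitive intercepts/slopes follow the direction (not magnitude) of the
#' corresponding subgroup gradient: the vascular extreme starts near the
#' cohort average and declines fastest in executive function and processing
#' speed; the Alzheimer's-like extreme starts impaired across domains,
#' notably memory. Hazards are illustrative (the source data report no
#' per-subtype hazards) and reproduce only the ordering of onset times.
#'
#' @return data frame with one row per subtype.
#' @export
default_subtype_profiles <- function() {
  data.frame(
    subtype = 1:4,
    weight = c(5, 2, 5, 10),
    wmh_mult = c(2.0, 1.4, 1.0, 0.5),
    lacune_mult = c(2.5, 1.5, 1.2, 0.6),
    hipp_gm_extra = c(0.00, 0.04, 0.08, 0.12),
    hipp_rate = c(0.005, 0.015, 0.025, 0.040),
    global_rate = c(0.010, 0.008, 0.006, 0.006),
    jac_amp = c(0.12, 0.10, 0.10, 0.15),
    jac_rois = I(list(c("striatum", "frontal_wm"),
                      c("thalamus", "frontal_wm"),
                      c("hippocampus", "thalamus"),
                      "hippocampus")),
    hazard = c(0.15, 0.35, 0.40, 0.35),
    cog_int_ef = c(-0.5, -1.2, -1.0, -1.5),
    cog_int_ps = c(-0.4, -1.4, -0.8, -1.5),
    cog_int_wm = c(0.0, -0.2, 0.1, -0.8),
    cog_int_ltm = c(0.0, -0.4, -0.2, -0.8),
    cog_int_global = c(-0.3, -1.0, -0.6, -1.2),
    cog_slope_ef = c(-0.30, -0.15, -0.12, -0.18),
    cog_slope_ps = c(-0.35, -0.15, -0.10, -0.18),
    cog_slope_wm = c(-0.05, -0.08, -0.08, -0.20),
    cog_slope_ltm = c(-0.05, -0.08, -0.10, -0.22),
    cog_slope_global = c(-0.18, -0.12, -0.10, -0.20)
  )
}

COG_DOMAINS <- c("ef", "ps", "wm", "ltm", "global")

# non-convertor cognitive process: baseline means follow the non-dementia
# column of the baseline table; slow decline
nonconvertor_cog <- function() {
  list(int = c(ef = -0.78, ps = -0.83, wm = -0.16, ltm = 0.01, global = -0.49),
       slope = c(ef = -0.03, ps = -0.03, wm = -0.02, ltm = -0.02, global = -0.03))
}

#' Deterministic template tissue maps
#'
#' The noise-free phantom anatomy shared by all synthetic subjects: a
#' spherical brain with a CSF rim, a white-matter core, a grey-matter shell,
#' subcortical GM nuclei at the atlas ROIs, deep white-matter ROIs, and a
#' low-level WMH field concentrated in frontal white matter and centrum
#' semiovale (WMH probability is carved out of WM so that
#' gm + wm + csf + wmh <= 1 holds voxel-wise).
#'
#' @param atlas a [make_atlas()] atlas.
#' @return named list of [volume()]s: `gm`, `wm`, `csf`, `wmh`, plus the
#'   binary `brain` mask.
#' @export
template_tissue <- function(atlas) {
  n <- atlas$grid_shape
  vs <- atlas$voxel_size_mm
  cc <- (n + 1) / 2
  d2 <- outer(outer((seq_len(n[1]) - cc[1])^2, (seq_len(n[2]) - cc[2])^2, "+"),
              (seq_len(n[3]) - cc[3])^2, "+")
  r_brain <- 0.42 * n[1]; r_inner <- 0.38 * n[1]; r_core <- 0.26 * n[1]
  brain <- d2 <= r_brain^2
  rim <- brain & d2 > r_inner^2
  core <- d2 <= r_core^2
  shell <- d2 <= r_inner^2 & !core

  gm <- wm <- csf <- wmh <- array(0, dim = n)
  csf[rim] <- 0.80; gm[rim] <- 0.10
  gm[shell] <- 0.70; wm[shell] <- 0.15; csf[shell] <- 0.10
  gm[core] <- 0.15; wm[core] <- 0.75; csf[core] <- 0.05

  labs <- vol_data(atlas$labels)
  gm_rois <- resolve_regions(atlas, c("putamen", "caudate", "hippocampus", "thalamus"))
  wm_rois <- resolve_regions(atlas, c("frontal_wm", "centrum_semiovale"))
  in_gm <- labs %in% gm_rois
  in_wm <- labs %in% wm_rois
  gm[in_gm] <- 0.80; wm[in_gm] <- 0.10; csf[in_gm] <- 0.05
  gm[in_wm] <- 0.08; wm[in_wm] <- 0.80; csf[in_wm] <- 0.05

  # WMH carved out of WM: low background in deep WM plus confluent lesion
  # cores in the frontal and centrum semiovale ROIs, graded radially from
  # 0.7 at the ROI centre to 0.1 at its edge so that a per-subject
  # binarisation threshold of 0.5 yields a non-zero baseline lesion volume
  # that grows smoothly under the convertor WMH excess
  wmh[core] <- 0.05
  for (l in resolve_regions(atlas, c("frontal_wm", "centrum_semiovale"))) {
    idx <- which(labs == l)
    pos <- arrayInd(idx, n)
    ctr <- colMeans(pos)
    dd <- sqrt(rowSums(sweep(pos, 2L, ctr)^2))
    rel <- if (max(dd) > 0) dd / max(dd) else dd
    wmh[idx] <- 0.1 + 0.6 * (1 - rel)
  }
  wmh <- wmh * (wm > 0)
  wm <- pmax(wm - wmh, 0)

  lapply(list(gm = gm, wm = wm, csf = csf, wmh = wmh, brain = brain * 1),
         volume, voxel_size_mm = vs, space_tag = atlas$space_tag)
}

# clip probabilities to [0,1] and renormalize voxels whose tissue sum
# exceeds 1 (can only happen through additive noise)
clip_tissue <- function(tis) {
  tis[c("gm", "wm", "csf", "wmh")] <- lapply(tis[c("gm", "wm", "csf", "wmh")],
                                             function(v) {
    volume_like(pmin(pmax(vol_data(v), 0), 1), v)
  })
  s <- vol_data(tis$gm) + vol_data(tis$wm) + vol_data(tis$csf) + vol_data(tis$wmh)
  over <- s > 1
  if (any(over)) {
    for (k in c("gm", "wm", "csf", "wmh")) {
      a <- vol_data(tis[[k]])
      a[over] <- a[over] / s[over]
      tis[[k]] <- volume_like(a, tis[[k]])
    }
  }
  tis
}

# draw lacunes for one subject: per-region Poisson counts, each lacune a
# 2-voxel (16 mm^3 at 2 mm) cluster fully inside its region
draw_lacunes <- function(atlas, rates) {
  labs <- vol_data(atlas$labels)
  mask <- array(0, dim = dim(labs))
  for (nm in names(rates)) {
    lam <- rates[[nm]]
    if (lam <= 0) next
    k <- stats::rpois(1L, lam)
    if (k == 0L) next
    reg_idx <- which(labs == atlas$names[[nm]])
    reg_arr <- arrayInd(reg_idx, dim(labs))
    for (i in seq_len(k)) {
      ctr <- sample.int(length(reg_idx), 1L)
      mask[reg_idx[ctr]] <- 1
      # add an in-region 6-neighbour so each lacune exceeds one voxel
      p <- reg_arr[ctr, ]
      nb <- sweep(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                  2L, p, `+`)
      ok <- which(apply(nb, 1L, function(q)
        all(q >= 1) && all(q <= dim(labs)) &&
          labs[q[1], q[2], q[3]] == atlas$names[[nm]]))
      if (length(ok))
        mask[matrix(nb[ok[sample.int(length(ok), 1L)], ], 1L)] <- 1
    }
  }
  volume(mask, atlas$voxel_size_mm, atlas$space_tag)
}

#' Simulate one synthetic subject
#'
#' Builds the full per-subject imaging stack from the deterministic template:
#' tissue probability maps with group/subtype effects applied before noise
#' (convertor GM in the target ROIs scaled by `1 - gm_reduction_fraction`,
#' WMH excess added in frontal WM, extra bilateral hippocampal GM loss by
#' subtype), Poisson lacunes, a Jacobian determinant map with planted
#' contraction in the subtype's atrophic ROIs, a true rate map, and a
#' divergence-map series following the mid-point convention
#' (`d_t = rate * (t - mean(t)) + noise`, so the series averages ~0 at the
#' subject's mean scan time).
#'
#' @param atlas a [make_atlas()] atlas.
#' @param effects an [effect_spec()].
#' @param group `"preVaD"` or `"non-convertor"`.
#' @param subtype integer 1-4 (convertors) or `NA`.
#' @param seed integer seed for this subject's randomness.
#' @param template optional precomputed [template_tissue()] list (shared
#'   across subjects for speed).
#' @param with character subset of `c("tissues", "jacobian", "divergence")`
#'   selecting which imaging outputs to generate.
#' @return object of class `svd_subject`.
#' @export
simulate_subject <- function(atlas, effects, group = "preVaD", subtype = 1L,
                             seed = 1L, template = NULL,
                             with = c("tissues", "jacobian", "divergence")) {
  stopifnot(group %in% c("preVaD", "non-convertor"))
  conv <- group == "preVaD"
  if (conv && !(subtype %in% effects$subtype_profiles$subtype))
    stop("unknown subtype id: ", subtype)
  prof <- if (conv) effects$subtype_profiles[
    effects$subtype_profiles$subtype == subtype, ] else NULL
  if (is.null(template)) template <- template_tissue(atlas)
  set.seed(seed)
  vs <- atlas$voxel_size_mm
  labs <- vol_data(atlas$labels)
  brain <- vol_data(template$brain) > 0
  out <- list(group = group, subtype = if (conv) subtype else NA_integer_)

  # scan schedule with dropout (baseline always kept; at least 2 visits)
  times <- seq(0, effects$n_timepoints - 1)
  if (length(times) > 1L && effects$dropout_prob > 0) {
    keep <- c(TRUE, stats::runif(length(times) - 1L) >= effects$dropout_prob)
    if (sum(keep) < 2L) keep[2L] <- TRUE
    times <- times[keep]
  }
  out$scan_times <- times

  if ("tissues" %in% with) {
    gm <- vol_data(template$gm); wm <- vol_data(template$wm)
    csf <- vol_data(template$csf); wmh <- vol_data(template$wmh)
    if (conv) {
      tgt <- labs %in% resolve_regions(atlas, effects$gm_rois)
      gm[tgt] <- gm[tgt] * (1 - effects$gm_reduction_fraction)
      if (prof$hipp_gm_extra > 0) {
        hip <- labs %in% resolve_regions(atlas, "hippocampus")
        gm[hip] <- gm[hip] * (1 - prof$hipp_gm_extra)
      }
      wtg <- labs %in% resolve_regions(atlas, effects$wmh_rois)
      add <- effects$wmh_excess * prof$wmh_mult
      wmh[wtg] <- wmh[wtg] + add
      wm[wtg] <- pmax(wm[wtg] - add, 0)
    }
    sd <- effects$noise_sd
    if (sd > 0) {
      nz <- function(a) a + stats::rnorm(length(a), sd = sd) * brain
      gm <- nz(gm); wm <- nz(wm); csf <- nz(csf); wmh <- nz(wmh)
    }
    tis <- clip_tissue(list(gm = volume(gm, vs), wm = volume(wm, vs),
                            csf = volume(csf, vs), wmh = volume(wmh, vs)))
    rates <- effects$lacune_rate[[group]]
    if (conv) rates <- rates * prof$lacune_mult
    tis$lacunes <- draw_lacunes(atlas, as.list(rates))
    out$tissues <- tis
  }

  # planted contraction field shared by the Jacobian and the rate map
  contraction <- NULL
  if (any(c("jacobian", "divergence") %in% with)) {
    contraction <- array(0, dim = dim(labs))
    if (conv) {
      jr <- labs %in% resolve_regions(atlas, unlist(prof$jac_rois))
      contraction[jr] <- prof$jac_amp
    }
  }
  if ("jacobian" %in% with) {
    jn <- effects$noise_sd / 2
    jac <- 1 - contraction +
      if (jn > 0) stats::rnorm(length(labs), sd = jn) * brain else 0
    out$jacobian <- volume(pmax(array(jac, dim(labs)), 0.05), vs)
  }
  if ("divergence" %in% with) {
    rate <- array(0, dim = dim(labs))
    g_rate <- if (conv) prof$global_rate else 0.002
    rate[brain] <- -g_rate
    if (conv) {
      hip <- labs %in% resolve_regions(atlas, "hippocampus")
      rate[hip] <- rate[hip] - prof$hipp_rate
    }
    out$true_rate <- volume(rate, vs)
    dn <- effects$noise_sd / 5
    tc <- times - mean(times)
    out$divergence <- list(times = times, maps = lapply(seq_along(times),
      function(i) {
        d <- rate * tc[i] +
          if (dn > 0) stats::rnorm(length(rate), sd = dn) * brain else 0
        volume(array(d, dim(rate)), vs)
      }))
  }
  class(out) <- "svd_subject"
  out
}

# draw an exponential conversion time truncated to (0, horizon] by
# inverse-CDF, so planted convertors always convert inside the horizon
rexp_truncated <- function(n, rate, horizon) {
  u <- stats::runif(n) * stats::pexp(horizon, rate)
  stats::qexp(u, rate)
}

#' Simulate a full synthetic cohort
#'
#' Generates the cohort table and per-subject imaging for the planted group
#' structure: `n_per_group` non-convertors and convertors, convertor
#' subtypes drawn in the default 5/2/5/10 proportions, demographics with
#' group-dependent means, annual cognitive visits with subtype-patterned
#' intercepts/slopes, and conversion times. Planted convertors draw their
#' event time from an exponential with their subtype's hazard truncated at
#' the horizon (so the planted group and the derived `converted` flag
#' coincide); planted non-convertors convert only if
#' `hazard_nonconvertor > 0`, and are otherwise administratively censored
#' at the horizon. Fully reproducible given `seed`.
#'
#' @param effects an [effect_spec()].
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param atlas optional atlas (built from `effects` geometry if omitted).
#' @param with imaging outputs to generate per subject (see
#'   [simulate_subject()]); use `character(0)` for a records-only cohort.
#' @return list with `cohort` (a [cohort_table()]), `subjects` (list of
#'   `svd_subject`), `atlas`, `template`, and `truth` (the planted
#'   parameters, for harnesses).
#' @export
simulate_cohort <- function(effects = effect_spec(), seed = 1L, atlas = NULL,
                            with = c("tissues", "jacobian", "divergence")) {
  stopifnot(all(effects$n_per_group >= 2L))
  if (is.null(atlas))
    atlas <- make_atlas(effects$grid_shape, effects$voxel_size_mm)
  template <- if (length(with)) template_tissue(atlas) else NULL
  n_nc <- effects$n_per_group[["non-convertor"]]
  n_cv <- effects$n_per_group[["preVaD"]]
  n <- n_nc + n_cv
  set.seed(seed)

  # planted subtypes in the default mixture proportions
  w <- effects$subtype_profiles$weight
  counts <- floor(n_cv * w / sum(w))
  while (sum(counts) < n_cv) {
    i <- which.max(n_cv * w / sum(w) - counts)
    counts[i] <- counts[i] + 1L
  }
  subtypes <- sample(rep(effects$subtype_profiles$subtype, counts))
  group <- c(rep("non-convertor", n_nc), rep("preVaD", n_cv))
  subtype <- c(rep(NA_integer_, n_nc), subtypes)
  ids <- sprintf("S%03d", seq_len(n))

  # demographics with group-dependent means
  conv <- group == "preVaD"
  age <- round(stats::rnorm(n, mean = ifelse(conv, 73.2, 69.5),
                            sd = ifelse(conv, 9.4, 9.5)), 1)
  sex <- ifelse(stats::runif(n) < ifelse(conv, 0.77, 0.61), "male", "female")
  nart <- round(stats::rnorm(n, mean = ifelse(conv, 93, 100), sd = 15), 1)
  rankin <- pmin(pmax(round(stats::rnorm(n, ifelse(conv, 1.6, 1.1),
                                         ifelse(conv, 1.5, 1.0))), 0), 5)
  mmse <- pmin(pmax(round(stats::rnorm(n, ifelse(conv, 26, 29),
                                       ifelse(conv, 3, 1.5))), 16), 30)

  # conversion outcome
  event_time <- rep(effects$horizon, n)
  converted <- rep(FALSE, n)
  for (i in which(conv)) {
    h <- effects$subtype_profiles$hazard[
      effects$subtype_profiles$subtype == subtype[i]]
    event_time[i] <- rexp_truncated(1L, h, effects$horizon)
    converted[i] <- TRUE
  }
  if (effects$hazard_nonconvertor > 0) {
    t_nc <- stats::rexp(sum(!conv), effects$hazard_nonconvertor)
    converted[!conv] <- t_nc <= effects$horizon
    event_time[!conv] <- pmin(t_nc, effects$horizon)
  }
  if (effects$quantize_conversion) {
    ev <- converted
    event_time[ev] <- floor(event_time[ev]) + 0.5  # mid-point between visits
  }
  event_time <- pmax(event_time, 1e-3)

  # per-subject seeds drawn from the master stream, so cohorts generated
  # under different master seeds share no per-subject noise fields
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  visits_list <- list()
  cog_nc <- nonconvertor_cog()
  scan_times <- vector("list", n)
  tiv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- simulate_subject(atlas, effects, group[i],
                          if (conv[i]) subtype[i] else 1L,
                          seed = subject_seeds[i], template = template,
                          with = with)
    s$id <- ids[i]
    subjects[[i]] <- s
    scan_times[[i]] <- s$scan_times
    if (!is.null(s$tissues)) {
      vv <- voxel_volume_mm3(s$tissues$gm)
      tiv[i] <- (sum(vol_data(s$tissues$gm) >= 0.2) +
                 sum(vol_data(s$tissues$wm) >= 0.2) +
                 sum(vol_data(s$tissues$wmh) >= 0.2) +
                 sum(vol_data(s$tissues$csf) >= 0.2)) * vv
    }
    # cognition: linear-in-time z-scores at the subject's visits
    if (conv[i]) {
      p <- effects$subtype_profiles[effects$subtype_profiles$subtype == subtype[i], ]
      ints <- unlist(p[paste0("cog_int_", COG_DOMAINS)])
      slps <- unlist(p[paste0("cog_slope_", COG_DOMAINS)])
    } else {
      ints <- cog_nc$int; slps <- cog_nc$slope
    }
    ints <- ints + stats::rnorm(5L, sd = 0.5)
    slps <- slps + stats::rnorm(5L, sd = 0.05)
    tt <- s$scan_times
    sc <- outer(tt, slps) + rep(ints, each = length(tt)) +
      stats::rnorm(length(tt) * 5L, sd = 0.3)
    colnames(sc) <- COG_DOMAINS
    visits_list[[i]] <- data.frame(id = ids[i], time = tt, sc)
  }
  # TIV for records-only cohorts: plausible phantom-scale draw
  if (all(is.na(tiv)))
    tiv <- round(stats::rnorm(n, 75000, 5000))

  subj_df <- data.frame(id = ids, age = age, sex = sex, nart = nart,
                        rankin = rankin, tiv_mm3 = tiv, mmse = mmse,
                        converted = converted, event_time = event_time,
                        subtype = subtype, stringsAsFactors = FALSE)
  subj_df$scan_times <- scan_times
  cohort <- cohort_table(subj_df, do.call(rbind, visits_list),
                         horizon = effects$horizon)
  list(cohort = cohort, subjects = subjects, atlas = atlas,
       template = template,
       truth = list(effects = effects, seed = seed,
                    subtype = stats::setNames(subtype, ids),
                    group = stats::setNames(group, ids)))
}

#' Simulate censored exponential survival data
#'
#' Minimal survival generator used for calibration of the Kaplan-Meier and
#' log-rank machinery: exponential event times with administrative
#' censoring at `horizon`.
#'
#' @param n number of subjects.
#' @param hazard events per year.
#' @param horizon censoring time in years (`Inf` for none).
#' @param seed integer seed.
#' @return data frame with `time` (observed) and `event` (logical).
#' @export
simulate_survival <- function(n, hazard, horizon = 5, seed = 1L) {
  stopifnot(hazard > 0, n >= 1)
  set.seed(seed)
  t_true <- stats::rexp(n, hazard)
  data.frame(time = pmin(t_true, horizon), event = t_true <= horizon)
}
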