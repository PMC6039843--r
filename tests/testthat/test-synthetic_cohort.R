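test_that("atlas has >= 10 mirrored, disjoint, non-empty regions and is deterministic", {
  at <- make_atlas()
  expect_gte(length(at$names), 10L)
  labs <- vd(at$labels)
  counts <- table(labs[labs > 0])
  expect_true(all(counts > 0))
  # mirrored pairs have identical voxel counts
  for (base in unique(sub("_[LR]$", "", names(at$names)))) {
    expect_equal(sum(labs == at$names[[paste0(base, "_L")]]),
                 sum(labs == at$names[[paste0(base, "_R")]]),
                 info = base)
  }
  expect_identical(vd(make_atlas()$labels), labs)
  expect_error(make_atlas(c(8L, 8L, 8L)), "grid too small")
})

test_that("region-set resolution handles sides, composites and unions", {
  at <- make_atlas()
  expect_length(resolve_regions(at, "striatum_L"), 2L)
  expect_length(resolve_regions(at, "striatum"), 4L)
  expect_equal(resolve_regions(at, "striatum + hippocampus"),
               sort(c(resolve_regions(at, "striatum"),
                      resolve_regions(at, "hippocampus"))))
  expect_error(resolve_regions(at, "amygdala"), "unknown region")
})

test_that("template tissue probabilities are valid and sum to at most 1", {
  tpl <- template_tissue(make_atlas())
  s <- vd(tpl$gm) + vd(tpl$wm) + vd(tpl$csf) + vd(tpl$wmh)
  expect_lte(max(s), 1 + 1e-12)
  for (k in c("gm", "wm", "csf", "wmh")) {
    expect_gte(min(vd(tpl[[k]])), 0)
    expect_lte(max(vd(tpl[[k]])), 1)
  }
})

test_that("noiseless convertor GM is exactly (1 - reduction) x template in target ROIs", {
  at <- make_atlas(); tpl <- template_tissue(at)
  eff <- effect_spec(noise_sd = 0, dropout_prob = 0)
  s <- simulate_subject(at, eff, "preVaD", subtype = 1L, seed = 3,
                        template = tpl)
  m <- vd(roi_mask(at, "striatum_L")) > 0
  expect_equal(vd(s$tissues$gm)[m], 0.85 * vd(tpl$gm)[m], tolerance = 1e-12)
  # contralateral striatum untouched
  mr <- vd(roi_mask(at, "striatum_R")) > 0
  expect_equal(vd(s$tissues$gm)[mr], vd(tpl$gm)[mr], tolerance = 1e-12)
  # tissue sum constraint holds after effects
  ts <- vd(s$tissues$gm) + vd(s$tissues$wm) + vd(s$tissues$csf) +
    vd(s$tissues$wmh)
  expect_lte(max(ts), 1 + 1e-12)
})

test_that("noiseless divergence series is an exact line through the true rate map", {
  at <- make_atlas()
  eff <- effect_spec(noise_sd = 0, dropout_prob = 0)
  s <- simulate_subject(at, eff, "preVaD", subtype = 4L, seed = 5)
  rm <- fit_voxel_rates(s$divergence)
  expect_equal(vd(rm$slope), vd(s$true_rate), tolerance = 1e-12)
  # mid-point convention: the series averages ~0 at the mean scan time
  avg <- Reduce(`+`, lapply(s$divergence$maps, vd)) / length(s$divergence$maps)
  expect_lt(max(abs(avg)), 1e-12)
})

test_that("jacobians are positive and carry the planted subtype contraction", {
  at <- make_atlas()
  eff <- effect_spec(noise_sd = 0)
  s4 <- simulate_subject(at, eff, "preVaD", subtype = 4L, seed = 2)
  expect_gt(min(vd(s4$jacobian)), 0)
  hip <- vd(roi_mask(at, "hippocampus")) > 0
  expect_lt(mean(vd(s4$jacobian)[hip]), 1)
  nc <- simulate_subject(at, eff, "non-convertor", seed = 2)
  expect_equal(mean(vd(nc$jacobian)[hip]), 1, tolerance = 1e-12)
  expect_error(simulate_subject(at, eff, "preVaD", subtype = 9L), "unknown subtype")
})

test_that("zero lacune rates give an empty lacune mask", {
  at <- make_atlas()
  zero <- list("non-convertor" = c(putamen_L = 0), "preVaD" = c(putamen_L = 0))
  eff <- effect_spec(noise_sd = 0, lacune_rate = zero)
  s <- simulate_subject(at, eff, "preVaD", subtype = 1L, seed = 1)
  expect_equal(sum(vd(s$tissues$lacunes)), 0)
})

test_that("cohorts are byte-identical under a fixed seed", {
  eff <- null_effect_spec(c("non-convertor" = 4L, "preVaD" = 4L))
  a <- simulate_cohort(eff, seed = 123, with = "tissues")
  b <- simulate_cohort(eff, seed = 123, with = "tissues")
  expect_identical(a$cohort$subjects, b$cohort$subjects)
  expect_identical(lapply(a$subjects, function(s) vd(s$tissues$gm)),
                   lapply(b$subjects, function(s) vd(s$tissues$gm)))
  c2 <- simulate_cohort(eff, seed = 124, with = "tissues")
  expect_false(identical(a$cohort$subjects$age, c2$cohort$subjects$age))
})

test_that("zero non-convertor hazard yields zero convertors among planted non-convertors", {
  eff <- null_effect_spec(c("non-convertor" = 20L, "preVaD" = 4L))
  sim <- simulate_cohort(eff, seed = 9, with = character(0))
  s <- sim$cohort$subjects
  planted_nc <- names(sim$truth$group)[sim$truth$group == "non-convertor"]
  expect_false(any(s$converted[s$id %in% planted_nc]))
  # planted convertors all convert inside the horizon (truncated draw)
  expect_true(all(s$converted[!s$id %in% planted_nc]))
  expect_true(all(s$event_time <= 5))
})

test_that("observed convertor fraction matches the configured fraction (binomial oracle)", {
  eff <- null_effect_spec(c("non-convertor" = 20L, "preVaD" = 5L))
  fracs <- vapply(1:100, function(i) {
    mean(simulate_cohort(eff, seed = 200 + i,
                         with = character(0))$cohort$subjects$converted)
  }, numeric(1))
  p_cfg <- 5 / 25
  se <- sqrt(p_cfg * (1 - p_cfg) / (25 * 100))
  expect_lte(abs(mean(fracs) - p_cfg), 3 * se + 1e-12)
})

test_that("per-ROI lacune presence matches the Poisson oracle over many subjects", {
  at <- make_atlas()
  eff <- effect_spec(noise_sd = 0, dropout_prob = 0)
  lam <- default_lacune_rates()[["non-convertor"]]
  set.seed(41)
  n <- 250L
  present <- matrix(0, n, length(lam), dimnames = list(NULL, names(lam)))
  for (i in seq_len(n)) {
    s <- simulate_subject(at, eff, "non-convertor", seed = 5000 + i,
                          with = "tissues")
    m <- vd(s$tissues$lacunes) > 0
    labs <- vd(at$labels)
    present[i, ] <- vapply(names(lam), function(nm)
      as.numeric(any(m & labs == at$names[[nm]])), numeric(1))
  }
  for (nm in names(lam)) {
    p <- 1 - exp(-lam[[nm]])     # presence probability under Poisson counts
    se <- sqrt(p * (1 - p) / n)
    expect_lte(abs(mean(present[, nm]) - p), 3 * se + 0.02)
  }
})

test_that("exponential survival generator reaches the closed-form median at scale", {
  sv <- simulate_survival(2000, hazard = 0.3, horizon = 5, seed = 1)
  km <- kaplan_meier(sv$time, sv$event)
  expect_lte(abs(km$median - log(2) / 0.3) / (log(2) / 0.3), 0.05)
})
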