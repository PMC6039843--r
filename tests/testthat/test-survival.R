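test_that("threshold selection maximizes Youden's J with smallest-threshold ties", {
  # perfectly separated marker: any threshold in the gap attains J = 1
  marker <- c(1, 2, 3, 10, 11, 12)
  outcome <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  ts <- threshold_select(marker, outcome)
  expect_equal(ts$selected_j, 1)
  expect_equal(ts$selected, 10)   # smallest grid point achieving J = 1
  expect_error(threshold_select(rep(1, 6), outcome), "degenerate")
  expect_error(threshold_select(marker, rep(TRUE, 6)), "both outcome classes")
})

test_that("sensitivity/specificity curves match exhaustive counting on a hand fixture", {
  marker <- c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0)
  outcome <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  ts <- threshold_select(marker, outcome, grid = c(1, 2, 3, 4))
  for (r in seq_len(nrow(ts$table))) {
    th <- ts$table$threshold[r]
    pred <- marker >= th
    expect_equal(ts$table$sensitivity[r],
                 100 * sum(pred & outcome) / sum(outcome))
    expect_equal(ts$table$specificity[r],
                 100 * sum(!pred & !outcome) / sum(!outcome))
  }
  # monotone: sensitivity falls, specificity rises along the grid
  expect_true(all(diff(ts$table$sensitivity) <= 0))
  expect_true(all(diff(ts$table$specificity) >= 0))
})

test_that("an uninformative marker yields near-zero maximal J at large n", {
  set.seed(29)
  marker <- runif(4000)
  outcome <- runif(4000) < 0.3
  ts <- threshold_select(marker, outcome,
                         grid = seq(0.05, 0.95, by = 0.05))
  expect_lt(ts$selected_j, 0.08)
})

test_that("Kaplan-Meier matches closed forms without censoring", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  all_c <- kaplan_meier(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(all_c$survival == 1))
  expect_true(is.na(all_c$median))
  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)), "negative")
  # uncensored KM equals the empirical survival function
  set.seed(30)
  t <- rexp(50, 0.5)
  km2 <- kaplan_meier(t, rep(TRUE, 50))
  ecdf_surv <- sapply(km2$time, function(x) mean(t > x))
  expect_equal(km2$survival, ecdf_surv, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches the hand-computed product-limit table under censoring", {
  # subjects: event 1, censor 2, event 3, event 3, censor 4, event 5
  tms <- c(1, 2, 3, 3, 4, 5); ev <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  km <- kaplan_meier(tms, ev)
  # hand product-limit: S(1) = 5/6; S(3) = 5/6 * 2/4; S(5) = 5/12 * 0
  s_hand <- c(5 / 6, 5 / 6, 5 / 6 * 2 / 4, 5 / 6 * 2 / 4, 0)
  expect_equal(km$survival, s_hand, tolerance = 1e-12)
  expect_equal(km$median, 3)
  expect_equal(km_survival_at(km, 0.5), 1)
  expect_equal(km_survival_at(km, 3.5), 5 / 12, tolerance = 1e-12)
})

test_that("log-rank matches an event-by-event hand computation", {
  tms <- c(1, 2, 2, 3, 4, 1.5, 2.5, 3.5, 4.5, 5)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  grp <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(tms, ev, grp)
  # independent oracle: hypergeometric observed-minus-expected per event time
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(tms[ev]))) {
    at_risk <- tms >= tt
    n1 <- sum(at_risk & grp == "a"); n <- sum(at_risk)
    d <- sum(ev & tms == tt); d1 <- sum(ev & tms == tt & grp == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chisq, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # invariant to swapping group labels
  lr_swap <- logrank_test(tms, ev, rev(grp)[c(6:10, 1:5)])
  expect_equal(lr_swap$chisq, lr$chisq, tolerance = 1e-12)
  # identical groups: statistic ~ 0
  lr0 <- logrank_test(rep(tms[1:5], 2), rep(ev[1:5], 2), rep(c("a", "b"), 5))
  expect_lt(lr0$chisq, 1e-10)
  expect_gt(lr0$p, 0.99)
})

test_that("stratified analysis reports four strata with planted-hazard ordering", {
  hz <- c("positive/high" = 0.40, "positive/low" = 0.25,
          "negative/high" = 0.10, "negative/low" = 0.04)
  n <- 2000L
  dat <- do.call(rbind, Map(function(nm, h) {
    sv <- simulate_survival(n, h, horizon = 5,
                            seed = 1000 + round(1000 * h))
    data.frame(stratum = nm, time = sv$time, event = sv$event)
  }, names(hz), hz))
  pos <- grepl("^positive", dat$stratum)
  high <- grepl("high$", dat$stratum)
  svdp_vals <- ifelse(high, 6, 2)
  res <- stratified_analysis(pos, svdp_vals, threshold = 4,
                             dat$time, dat$event)
  cp <- setNames(res$strata$conversion_prob, res$strata$stratum)
  expect_true(cp["positive/high"] > cp["positive/low"] &&
                cp["positive/low"] > cp["negative/high"] &&
                cp["negative/high"] > cp["negative/low"])
  # conversion probabilities near the exponential truth 1 - exp(-5h)
  for (nm in names(hz))
    expect_lt(abs(cp[nm] - (1 - exp(-5 * hz[nm]))), 0.05)
  expect_lt(res$logrank$p, 1e-10)
})

test_that("degenerate strata are reported as missing, not errors", {
  tms <- c(1, 2, 3, 4); ev <- c(TRUE, TRUE, FALSE, TRUE)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  sv <- c(1, 2, 1.5, 2.5)
  expect_warning(res <- stratified_analysis(pos, sv, threshold = 2.5,
                                            tms, ev),
                 "single populated burden stratum")
  tab <- res$strata
  expect_true(is.na(tab$conversion_prob[tab$stratum == "positive/high"]))
  expect_error(stratified_analysis(pos, sv, 99, tms, ev), "outside")
})
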