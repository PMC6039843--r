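test_that("feature extraction has deterministic shape and ordering", {
  vols <- list(A = tiny_volume(1), B = tiny_volume(2), C = tiny_volume(3))
  mask <- tiny_volume(0); mask[c(1, 7, 33, 60, 100)] <- 1
  fe <- extract_features(vols, as_vol(vd(mask)))
  expect_equal(dim(fe$values), c(3L, 5L))
  expect_equal(rownames(fe$values), c("A", "B", "C"))
  expect_error(extract_features(vols, tiny_volume(0)), "empty")
  # union mask columns = concatenation of disjoint ROI columns up to order
  m1 <- tiny_volume(0); m1[1:10] <- 1
  m2 <- tiny_volume(0); m2[21:30] <- 1
  fu <- extract_features(vols, as_vol(vd(m1) + vd(m2)))
  f1 <- extract_features(vols, as_vol(vd(m1)))
  f2 <- extract_features(vols, as_vol(vd(m2)))
  expect_equal(fu$values, cbind(f1$values, f2$values))
})

test_that("masked features expose exactly the planted noiseless reduction", {
  at <- make_atlas()
  eff <- effect_spec(noise_sd = 0)
  cv <- simulate_subject(at, eff, "preVaD", 1L, seed = 1, with = "tissues")
  nc <- simulate_subject(at, eff, "non-convertor", seed = 2, with = "tissues")
  fe <- extract_features(list(cv = cv$tissues$gm, nc = nc$tissues$gm),
                         roi_mask(at, "striatum_L"))
  expect_equal(mean(fe$values["cv", ]) / mean(fe$values["nc", ]), 0.85,
               tolerance = 1e-12)
})

test_that("the metric suite reproduces hand-computable confusion arithmetic", {
  m <- classification_metrics(TP = 12, FP = 8, TN = 89, FN = 10)
  expect_equal(round(m$total_accuracy, 2), 84.87)
  expect_equal(round(m$sensitivity, 2), 54.55)
  expect_equal(round(m$specificity, 2), 91.75)
  expect_equal(round(m$ppv, 1), 60.0)
  expect_equal(round(m$npv, 1), 89.9)
  expect_equal(round(m$balanced_accuracy, 2), 73.15)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  # all-negative prediction at the 22/97 prevalence
  m0 <- classification_metrics(TP = 0, FP = 0, TN = 97, FN = 22)
  expect_equal(round(m0$total_accuracy, 1), 81.5)
  expect_equal(m0$balanced_accuracy, 50)
  expect_true(is.na(m0$ppv))          # undefined ratio reported missing
  # perfect prediction
  mp <- classification_metrics(22, 0, 97, 0,
                               decision_values = c(rep(1, 22), rep(-1, 97)),
                               labels = c(rep(TRUE, 22), rep(FALSE, 97)))
  expect_true(all(unlist(mp[c("total_accuracy", "balanced_accuracy",
                              "sensitivity", "specificity", "ppv", "npv")]) == 100))
  expect_equal(mp$auc, 1.0)
})

test_that("rank-based AUC gives ties half credit (Wilcoxon oracle)", {
  set.seed(18)
  dv <- c(1, 1, 0, 0, 2, -1, 1)
  lab <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  m <- classification_metrics(1, 1, 1, 1, dv, lab)
  n1 <- sum(lab); n0 <- sum(!lab)
  w <- sum(outer(dv[lab], dv[!lab], function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(m$auc, w / (n1 * n0), tolerance = 1e-12)
})

test_that("LOO prediction is perfect on widely separated clusters", {
  set.seed(19)
  n <- 16L
  X <- rbind(matrix(rnorm(n / 2 * 4, mean = 5), n / 2, 4),
             matrix(rnorm(n / 2 * 4, mean = -5), n / 2, 4))
  grp <- rep(c("preVaD", "non-convertor"), each = n / 2)
  res <- loo_predict(X, grp)
  expect_equal(res$metrics$total_accuracy, 100)
  expect_equal(res$metrics$balanced_accuracy, 100)
  expect_equal(res$metrics$auc, 1.0)
  expect_true(all(res$decision_values[1:(n / 2)] > 0))
})

test_that("SVM decision function matches the closed-form max-margin solution", {
  # separable toy set whose maximum-margin hyperplane is x1 = 0 with
  # margin 2 (support vectors (1,0) and (-1,0)): f(x) = x1 at large cost
  X <- rbind(c(1, 0), c(2, -1), c(2, 2), c(-1, 0), c(-2, 1), c(-2, -2))
  grp <- rep(c("preVaD", "non-convertor"), each = 3)
  probe <- matrix(c(0.5, 0, -3, 1, 0, 7), ncol = 2, byrow = TRUE)
  dv <- sapply(seq_len(nrow(probe)), function(i)
    svdstrat:::svm_decision(X, factor(grp), probe[i, , drop = FALSE],
                            "preVaD", C = 1e4))
  expect_equal(dv, probe[, 1], tolerance = 1e-6)
})

test_that("fold-wise confound removal and centering use training rows only", {
  set.seed(20)
  n <- 14L
  X <- matrix(rnorm(n * 6), n, 6)
  grp <- rep(c("preVaD", "non-convertor"), each = n / 2)
  cf <- cbind(age = rnorm(n), tiv = rnorm(n))
  res <- loo_predict(X, grp, cf)
  # independent refit of fold i with training-only parameters
  i <- 3L
  train <- setdiff(seq_len(n), i)
  Xc <- cbind(1, cf)
  beta <- solve(crossprod(Xc[train, ]), crossprod(Xc[train, ], X[train, ]))
  Z <- X - Xc %*% beta
  Z <- sweep(Z, 2, colMeans(Z[train, , drop = FALSE]))
  fit <- e1071::svm(x = Z[train, ], y = factor(grp[train]), kernel = "linear",
                    cost = 1, scale = FALSE, type = "C-classification")
  pr <- predict(fit, Z[i, , drop = FALSE], decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
  if (first != "preVaD") dv <- -dv
  expect_equal(res$decision_values[i], unname(dv), tolerance = 1e-10)
  # the fold-i training model is a function of the training rows only:
  # perturbing the held-out row moves fold i's decision exactly as the
  # unchanged training model dictates
  X2 <- X; X2[i, ] <- X2[i, ] + 100
  res2 <- loo_predict(X2, grp, cf)
  Z2 <- X2 - Xc %*% beta                      # same training-fold beta
  Z2 <- sweep(Z2, 2, colMeans(Z2[train, , drop = FALSE]))
  pr2 <- predict(fit, Z2[i, , drop = FALSE], decision.values = TRUE)
  dv2 <- drop(attr(pr2, "decision.values"))
  if (first != "preVaD") dv2 <- -dv2
  expect_equal(res2$decision_values[i], unname(dv2), tolerance = 1e-8)
})

test_that("permutation p-values hit their floor and ceiling", {
  set.seed(22)
  n <- 12L
  X <- rbind(matrix(rnorm(n / 2 * 3, 6), n / 2, 3),
             matrix(rnorm(n / 2 * 3, -6), n / 2, 3))
  grp <- rep(c("preVaD", "non-convertor"), each = n / 2)
  pv <- permutation_pvalue(X, grp, n_permutations = 99L, seed = 4)
  expect_equal(pv$observed, 100)
  expect_lte(pv$p, (1 + sum(pv$null >= 100)) / 100)
  expect_gte(pv$p, 1 / 100)                     # permutation floor
  # worst case: an observed statistic below every permuted value gives p = 1
  pv2 <- permutation_pvalue(X, grp, n_permutations = 99L, seed = 4,
                            statistic = function(r)
                              -r$metrics$balanced_accuracy)
  expect_equal(pv2$p, 1)
})

test_that("ROI prediction table is deterministic and ranks planted ROIs first", {
  eff <- effect_spec(n_per_group = c("non-convertor" = 12L, "preVaD" = 10L))
  sim <- simulate_cohort(eff, seed = 55, with = "tissues")
  grp <- as.character(sim$cohort$subjects$group)
  gm <- lapply(sim$subjects, function(s) s$tissues$gm)
  tab <- roi_prediction_table(
    gm, grp, roi_sets = c("striatum + hippocampus", "centrum_semiovale"),
    atlas = sim$atlas)
  expect_equal(nrow(tab), 2L)
  expect_gte(tab$balanced_accuracy[1], tab$balanced_accuracy[2])
  # identical features under two names give identical rows
  tab2 <- roi_prediction_table(gm, grp,
                               roi_sets = c("thalamus", "thalamus"),
                               atlas = sim$atlas)
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
  expect_equal(nrow(roi_prediction_table(gm, grp)), 0L)
  expect_error(roi_prediction_table(gm, grp, roi_sets = "amygdala",
                                    atlas = sim$atlas), "unknown region")
})
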