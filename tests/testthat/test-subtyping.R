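test_that("subject similarity follows the correlation-then-distance construction", {
  set.seed(23)
  base <- rnorm(20)
  X <- rbind(a = base, b = base, c = rnorm(20))
  D <- subject_similarity(X)
  expect_equal(D["a", "b"], 0, tolerance = 1e-12)
  expect_true(isSymmetric(D))
  # three mutually orthogonal (zero-correlation) subjects: rows of the
  # identity correlation matrix are distance sqrt(2) apart
  O <- rbind(c(1, -1, 1, -1, 0, 0), c(1, 1, -1, -1, 0, 0),
             c(0, 0, 0, 0, 1, -1))
  DO <- subject_similarity(O)
  off <- DO[upper.tri(DO)]
  expect_equal(off, rep(sqrt(2), 3), tolerance = 1e-12)
  expect_error(subject_similarity(rbind(a = rep(1, 5), b = rnorm(5),
                                        c = rnorm(5))),
               "zero-variance.*a")
})

test_that("similarity matches a double-loop brute-force oracle", {
  set.seed(24)
  X <- matrix(rnorm(5 * 30), 5, 30)
  D <- subject_similarity(X)
  R <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) R[i, j] <- cor(X[i, ], X[j, ])
  for (i in 1:5) for (j in 1:5) {
    d_ij <- sqrt(sum((R[i, ] - R[j, ])^2))
    expect_equal(D[i, j], d_ij, tolerance = 1e-12)
  }
})

test_that("per-subject affine rescaling of voxel vectors leaves distances unchanged", {
  set.seed(25)
  X <- matrix(rnorm(6 * 40), 6, 40)
  a <- runif(6, 0.5, 3); b <- rnorm(6)
  X2 <- X * a + b   # row-wise affine maps preserve Pearson rows
  expect_equal(subject_similarity(X2), subject_similarity(X),
               tolerance = 1e-10)
})

test_that("Ward linkage merges tight pairs first with monotone heights", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  D <- as.matrix(dist(X)); dimnames(D) <- list(1:4, 1:4)
  tree <- ward_linkage(D)
  expect_true(all(diff(tree$merges$height) >= -1e-12))
  first_two <- tree$merges[1:2, c("node_a", "node_b")]
  pairs <- apply(first_two, 1, function(r) paste(sort(-r), collapse = "+"))
  expect_setequal(pairs, c("1+2", "3+4"))
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(ward_linkage(Dbad), "symmetric")
})

test_that("the two-cluster cut matches exhaustive minimum within-cluster variance", {
  set.seed(26)
  X <- matrix(rnorm(6 * 4), 6, 4)
  D <- as.matrix(dist(X)); dimnames(D) <- list(letters[1:6], letters[1:6])
  lab <- cut_tree(ward_linkage(D), 2)
  wss <- function(assign) {
    sum(sapply(unique(assign), function(g) {
      Z <- X[assign == g, , drop = FALSE]
      sum(sweep(Z, 2, colMeans(Z))^2)
    }))
  }
  # exhaustive search over all 2-partitions
  best <- Inf; best_assign <- NULL
  for (code in 1:(2^5 - 1)) {
    assign <- c(0, as.integer(intToBits(code))[1:5])
    if (length(unique(assign)) == 2) {
      w <- wss(assign)
      if (w < best) { best <- w; best_assign <- assign }
    }
  }
  expect_equal(adjusted_rand_index(lab, best_assign), 1)
})

test_that("tree cutting is deterministic with k = 1 and k = n limits", {
  set.seed(27)
  X <- matrix(rnorm(5 * 8), 5, 8)
  tree <- ward_linkage(subject_similarity(X))
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 5))
  expect_equal(sort(unname(cut_tree(tree, 5))), 1:5)
  # labels numbered by dendrogram left-to-right order
  lab <- cut_tree(tree, 3)
  expect_equal(min(lab), 1L); expect_equal(max(lab), 3L)
  first_idx <- sapply(1:3, function(g) min(which(lab[tree$hclust$order] == g)))
  expect_true(all(diff(first_idx) > 0))
})

test_that("clustering is invariant to subject order up to relabeling", {
  set.seed(28)
  eff <- effect_spec(n_per_group = c("non-convertor" = 2L, "preVaD" = 12L),
                     grid_shape = c(16L, 16L, 16L))
  at <- make_atlas(c(16L, 16L, 16L))
  sim <- simulate_cohort(eff, seed = 66, atlas = at, with = "jacobian")
  conv <- which(sim$cohort$subjects$converted)
  jac <- lapply(sim$subjects[conv], function(s) s$jacobian)
  names(jac) <- sim$cohort$subjects$id[conv]
  brain <- make_brain_mask(c(16L, 16L, 16L))
  lab1 <- cut_tree(ward_linkage(subject_similarity(
    extract_features(jac, brain))), 4)
  perm <- sample(length(jac))
  lab2 <- cut_tree(ward_linkage(subject_similarity(
    extract_features(jac[perm], brain))), 4)
  expect_equal(adjusted_rand_index(lab1[names(lab2)], lab2), 1)
})

test_that("subgroup summaries aggregate exactly on a hand-computed fixture", {
  subj <- data.frame(
    id = sprintf("P%02d", 1:10),
    age = c(60, 62, 64, 70, 72, 74, 80, 82, 84, 86),
    sex = rep(c("male", "female"), 5),
    nart = seq(90, 108, by = 2), rankin = rep(1, 10),
    tiv_mm3 = rep(7e4, 10), mmse = c(29, 28, 27, 26, 25, 24, 23, 22, 21, 20),
    converted = rep(TRUE, 10), event_time = seq(1, 4.6, by = 0.4),
    stringsAsFactors = FALSE)
  co <- cohort_table(subj)
  labels <- setNames(rep(1:2, each = 5), subj$id)
  summ <- subgroup_summary(labels, co)
  expect_equal(summ$n, c(5L, 5L))
  expect_equal(summ$age_mean, c(mean(subj$age[1:5]), mean(subj$age[6:10])))
  expect_equal(summ$age_sd, c(sd(subj$age[1:5]), sd(subj$age[6:10])))
  expect_equal(summ$mmse_mean, c(27, 22))
  expect_equal(summ$male_pct, c(60, 40))
  # identical subjects give zero SDs
  same <- subj; same$age <- 70; same$mmse <- 25; same$nart <- 100
  same$event_time <- 3
  s2 <- subgroup_summary(labels, cohort_table(same))
  expect_equal(s2$age_sd, c(0, 0))
  expect_equal(s2$onset_years_sd, c(0, 0))
  expect_error(subgroup_summary(labels[1:8], co), "missing")
})

test_that("planted vascular and Alzheimer-like extremes order SVDp as constructed", {
  at <- make_atlas()
  eff <- effect_spec(noise_sd = 0)
  s1 <- simulate_subject(at, eff, "preVaD", 1L, seed = 1, with = "tissues")
  s4 <- simulate_subject(at, eff, "preVaD", 4L, seed = 1, with = "tissues")
  v1 <- volumetrics_row(s1$tissues)
  v4 <- volumetrics_row(s4$tissues)
  expect_gt(v1$svdp_percent, v4$svdp_percent)
})
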