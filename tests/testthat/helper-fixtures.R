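# shared fixtures: everything is generated in code at test time

vd <- svdstrat:::vol_data

# small constant-filled volume
tiny_volume <- function(fill = 0, dims = c(5L, 5L, 5L), vs = 1) {
  volume(array(fill, dim = dims), voxel_size_mm = vs)
}

# volume from a vector/array, 1 mm voxels
as_vol <- function(a, dims = NULL, vs = 1) {
  if (!is.null(dims)) a <- array(a, dim = dims)
  volume(a, voxel_size_mm = vs)
}

# a valid 3-subject cohort data frame
tiny_cohort_df <- function() {
  data.frame(id = c("A", "B", "C"), age = c(70, 65, 72),
             sex = c("male", "female", "male"), nart = c(100, 95, 105),
             rankin = c(1, 0, 2), tiv_mm3 = c(7e4, 7.2e4, 6.9e4),
             mmse = c(29, 28, 27), converted = c(FALSE, TRUE, FALSE),
             event_time = c(5, 3.2, 5),
             scan_times = c("0;1;2", "0;1", "0;1;2;3"),
             stringsAsFactors = FALSE)
}

# effect spec with every group effect switched off (global null), used for
# calibration tests; group sizes and grid scaled for test runtime
null_effect_spec <- function(n_per_group = c("non-convertor" = 15L,
                                             "preVaD" = 15L),
                             grid_shape = c(16L, 16L, 16L), ...) {
  prof <- default_subtype_profiles()
  prof$hipp_gm_extra <- 0
  prof$jac_amp <- 0
  prof$hipp_rate <- 0          # equal planted rates in both groups
  prof$global_rate <- 0.002
  prof$wmh_mult <- 1
  prof$lacune_mult <- 1
  effect_spec(n_per_group = n_per_group, gm_reduction_fraction = 0,
              wmh_excess = 0, subtype_profiles = prof,
              grid_shape = grid_shape, ...)
}

# wrap a plain matrix as a feature object on a synthetic 1-D mask
matrix_features <- function(Y) {
  v <- ncol(Y)
  structure(list(values = Y, mask = volume(array(1, c(v, 1L, 1L))),
                 voxel_idx = seq_len(v)),
            class = "svd_features")
}

# brute-force dense 3-D Gaussian convolution (independent oracle)
dense_gauss_conv <- function(a, fwhm, vs = 1) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  r <- max(1L, ceiling(4 * sigma))
  off <- -r:r
  k1 <- dnorm(off, sd = sigma); k1 <- k1 / sum(k1)
  d <- dim(a)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (dx in off) for (dy in off) for (dz in off) {
      p <- c(i + dx, j + dy, k + dz)
      if (all(p >= 1) && all(p <= d))
        acc <- acc + a[p[1], p[2], p[3]] *
          k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
    }
    out[i, j, k] <- acc
  }
  out
}
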