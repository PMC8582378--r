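test_that("bin grid construction matches the analytic cases", {
  # the printed real-cohort extremes at width 3 give 1232 bins
  ext <- rbind(c(799.7571411132812, 4493.67919921875),
               c(800.1551513671875, 4496.83984375))
  expect_identical(compute_bin_spec(ext, 3)$n_bins, 1232L)
  # single bin
  expect_identical(compute_bin_spec(c(0, 10), 10)$n_bins, 1L)
  # two bins; centers agree with an independent linear-spacing oracle
  bs <- compute_bin_spec(c(100, 106), 3)
  expect_identical(bs$n_bins, 2L)
  expect_equal(bs$centers, seq(100, 106, length.out = 2))
  bs5 <- compute_bin_spec(c(0, 100), 20)
  expect_equal(bs5$centers, seq(0, 100, length.out = 5))
  expect_error(compute_bin_spec(c(10, 10), 3), "degenerate")
})

test_that("bin grid construction is deterministic and exact on reruns", {
  ext <- matrix(c(799.7571411132812, 4493.67919921875,
                  800.1551513671875, 4496.83984375), 2, byrow = TRUE)
  a <- compute_bin_spec(ext, 3)
  b <- compute_bin_spec(ext, 3)
  expect_identical(a, b)
})

test_that("nearest-bin summation matches the hand-worked example", {
  bs <- compute_bin_spec(c(100, 106), 3)
  s <- msi_spectrum(c(100.1, 101.4, 102.9, 105.9), c(1, 2, 3, 4),
                    c(1L, 1L), "t")
  expect_equal(as.numeric(bin_spectrum(s, bs)), c(6, 4))
  z <- msi_spectrum(c(100.1, 101.4), c(0, 0), c(1L, 1L), "t")
  expect_equal(as.numeric(bin_spectrum(z, bs)), c(0, 0))
})

test_that("bin assignment agrees with a brute-force nearest-center oracle", {
  set.seed(13)
  bs <- compute_bin_spec(c(800, 950), 3)
  for (rep in 1:5) {
    s <- random_spectrum(200, 799, 951)  # includes out-of-range points
    oracle <- vapply(s$mz, function(m)
      which.min(abs(m - bs$centers)), integer(1))
    expect_identical(msitma:::bin_assign(s$mz, bs), oracle)
  }
})

test_that("binning conserves total intensity and ignores point order", {
  set.seed(14)
  bs <- compute_bin_spec(c(800, 1100), 3)
  for (rep in 1:10) {
    s <- random_spectrum(500)
    v <- bin_spectrum(s, bs)
    expect_lt(abs(sum(v) - sum(s$intensity)) / sum(s$intensity), 1e-6)
  }
  # permutation invariance: shuffle the points, same feature vector
  s <- random_spectrum(300)
  perm <- sample(length(s$mz))
  idx <- msitma:::bin_assign(s$mz, bs)
  v1 <- numeric(bs$n_bins)
  for (i in seq_along(idx)) v1[idx[i]] <- v1[idx[i]] + s$intensity[i]
  v2 <- numeric(bs$n_bins)
  for (i in perm) v2[idx[i]] <- v2[idx[i]] + s$intensity[i]
  expect_equal(v1, v2)
  expect_equal(as.numeric(bin_spectrum(s, bs)), v1)
})

test_that("square-root transform is exact, monotone and guarded", {
  expect_equal(as.numeric(sqrt_transform(c(0, 1))), c(0, 1))
  expect_equal(as.numeric(sqrt_transform(c(4, 9, 16))), c(2, 3, 4))
  set.seed(15)
  v <- rexp(50)
  out <- sqrt_transform(v)
  expect_identical(order(out), order(v))
  expect_true(attr(out, "transformed"))
  expect_error(sqrt_transform(out), "already")
  expect_error(sqrt_transform(c(-1, 2)), "negative")
})

test_that("feature matrix has one labelled row per spectrum", {
  g1 <- structure(list(
    group_id = "A", patient_id = "P1", label = 1L, tma_id = "tmaA",
    spectra = lapply(1:3, function(i)
      make_spectrum(rexp(20), mz = seq(800, 819), coords = c(i, 1L)))),
    class = "tissue_group")
  g2 <- structure(list(
    group_id = "B", patient_id = "P2", label = 0L, tma_id = "tmaA",
    spectra = lapply(1:5, function(i)
      make_spectrum(rexp(20), mz = seq(800, 819), coords = c(i, 2L)))),
    class = "tissue_group")
  fm <- build_feature_matrix(list(g1, g2), width = 3, tic = FALSE,
                             apply_sqrt = FALSE)
  expect_identical(nrow(fm$x), 8L)
  expect_identical(fm$label, rep(c(1L, 0L), c(3L, 5L)))
  expect_identical(ncol(fm$x), fm$bin_spec$n_bins)
  # conservation row by row (pre-sqrt, no TIC)
  sums <- c(vapply(g1$spectra, function(s) sum(s$intensity), numeric(1)),
            vapply(g2$spectra, function(s) sum(s$intensity), numeric(1)))
  expect_equal(rowSums(fm$x), sums, tolerance = 1e-12)
  expect_error(build_feature_matrix(list()), "no tissue groups")
})

test_that("jittered twin axes harmonize onto near-identical features", {
  cfg <- sim_config(n_tmas = 2, patients_per_tma = 3, axis_points = 600,
                    mz_range = c(800, 890), axis_jitter = 1.4,
                    n_peaks = 10, n_effect = 0, noise_sdlog = 0,
                    baseline_sd = 0, spectra_per_core = c(2, 2), seed = 21)
  co <- generate_cohort(cfg)
  groups <- assign_groups(co$spectra, co$annotation, quiet = TRUE)
  fm <- build_feature_matrix(groups, width = 3, tic = TRUE,
                             apply_sqrt = FALSE)
  m1 <- colMeans(fm$x[fm$tma_id == "tma01", ])
  m2 <- colMeans(fm$x[fm$tma_id == "tma02", ])
  expect_gt(cor(m1, m2), 0.99)
})
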