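test_that("cohort generation is a deterministic function of the seed", {
  cfg <- sim_config(n_tmas = 2, patients_per_tma = 2, axis_points = 150,
                    n_peaks = 6, n_effect = 2, spectra_per_core = c(2, 3),
                    seed = 17)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_tmas = 2, patients_per_tma = 2,
                                   axis_points = 150, n_peaks = 6,
                                   n_effect = 2,
                                   spectra_per_core = c(2, 3), seed = 18))
  expect_false(identical(a$spectra, c2$spectra))
})

test_that("generated spectra are non-negative with positive ion counts
           and fully annotated", {
  cfg <- sim_config(n_tmas = 2, patients_per_tma = 3, axis_points = 200,
                    n_peaks = 8, n_effect = 2, seed = 19)
  co <- generate_cohort(cfg)
  for (s in co$spectra) {
    expect_true(all(s$intensity >= 0))
    expect_gt(sum(s$intensity), 0)
  }
  keys <- vapply(co$spectra, function(s)
    paste(s$tma_id, s$coords[1], s$coords[2]), character(1))
  ann_keys <- paste(co$annotation$tma_id, co$annotation$x, co$annotation$y)
  expect_setequal(keys, ann_keys)
  # labels are consistent within groups
  per_group <- tapply(co$annotation$label, co$annotation$group_id,
                      function(v) length(unique(v)))
  expect_true(all(per_group == 1L))
})

test_that("per-TMA axes differ by jitter but share the configured range", {
  cfg <- sim_config(n_tmas = 3, patients_per_tma = 2, axis_points = 300,
                    axis_jitter = 0.4, n_peaks = 6, n_effect = 0,
                    seed = 23)
  co <- generate_cohort(cfg)
  mins <- vapply(co$axes, min, numeric(1))
  maxs <- vapply(co$axes, max, numeric(1))
  expect_gt(length(unique(mins)), 1L)
  expect_true(all(abs(mins - 800) <= 0.4 + 1e-12))
  expect_true(all(abs(maxs - 1100) <= 0.4 + 1e-12))
})

test_that("the amplitude model decays with m/z", {
  cfg <- sim_config(n_tmas = 1, patients_per_tma = 4, axis_points = 1000,
                    n_peaks = 30, n_effect = 0, seed = 27)
  co <- generate_cohort(cfg)
  fit <- lm(log(amplitude) ~ mz, data = co$peaks)
  expect_lt(coef(fit)[["mz"]], 0)
  # binned mean intensity is higher in the low-m/z half
  groups <- assign_groups(co$spectra, co$annotation, quiet = TRUE)
  fm <- build_feature_matrix(groups, width = 3, tic = FALSE,
                             apply_sqrt = FALSE)
  B <- fm$bin_spec$n_bins
  lo <- mean(fm$x[, seq_len(B %/% 2)])
  hi <- mean(fm$x[, (B %/% 2 + 1):B])
  expect_gt(lo, hi)
})

test_that("every configured peak sits on a local maximum of the noise-free
           class mean", {
  cfg <- sim_config(n_tmas = 1, patients_per_tma = 2, axis_points = 1500,
                    n_peaks = 15, n_effect = 5, seed = 29)
  co <- generate_cohort(cfg)
  axis <- co$axes[[1]]
  # analytic positive-class mean: Gaussian basis times expected amplitudes
  fold <- ifelse(co$peaks$discriminating, cfg$fold_change, 1)
  Phi <- exp(-outer(axis, co$peaks$mz, "-")^2 / (2 * cfg$peak_sigma^2))
  mean_pos <- Phi %*% (co$peaks$amplitude * fold)
  for (p in co$peaks$mz) {
    i <- which.min(abs(axis - p))
    win <- max(1, i - 1):min(length(axis), i + 1)
    # the nearest axis point to the peak is a local maximum within one step
    expect_gte(mean_pos[i], max(mean_pos[win]) - 1e-9)
  }
})

test_that("class difference is confined to the discriminating peaks", {
  cfg <- sim_config(n_tmas = 1, patients_per_tma = 2, axis_points = 1200,
                    n_peaks = 12, n_effect = 3, fold_change = 3, seed = 31)
  co <- generate_cohort(cfg)
  axis <- co$axes[[1]]
  fold <- ifelse(co$peaks$discriminating, cfg$fold_change, 1)
  Phi <- exp(-outer(axis, co$peaks$mz, "-")^2 / (2 * cfg$peak_sigma^2))
  diff <- Phi %*% (co$peaks$amplitude * (fold - 1))
  disc_mz <- co$peaks$mz[co$peaks$discriminating]
  dist_to_disc <- vapply(axis, function(a) min(abs(a - disc_mz)),
                         numeric(1))
  far <- dist_to_disc > 5 * cfg$peak_sigma
  expect_lt(max(abs(diff[far])), max(abs(diff)) * 1e-3)
  near_idx <- vapply(disc_mz, function(p) which.min(abs(axis - p)),
                     integer(1))
  expect_true(all(abs(diff[near_idx]) > 0))
})

test_that("a null configuration has no class signal in expectation", {
  cfg <- sim_config(n_tmas = 1, patients_per_tma = 2, axis_points = 300,
                    n_peaks = 8, n_effect = 0, fold_change = 1, seed = 33)
  co <- generate_cohort(cfg)
  expect_identical(sum(co$peaks$discriminating), 0L)
  expect_length(co$effect$peak_mz, 0L)
})

test_that("discriminating peaks outside the axis range are rejected", {
  expect_error(sim_config(mz_range = c(800, 900), effect_mz = c(950)),
               "outside")
})

test_that("global intensity rescaling is invisible after TIC
           normalization", {
  cfg <- sim_config(n_tmas = 1, patients_per_tma = 2, axis_points = 200,
                    n_peaks = 6, n_effect = 2, seed = 35)
  co <- generate_cohort(cfg)
  groups <- assign_groups(co$spectra, co$annotation, quiet = TRUE)
  scaled <- lapply(groups, function(g) {
    g$spectra <- lapply(g$spectra, function(s) {
      s$intensity <- s$intensity * 7.3
      s
    })
    g
  })
  f1 <- build_feature_matrix(groups, width = 3, tic = TRUE,
                             apply_sqrt = FALSE)
  f2 <- build_feature_matrix(scaled, width = 3, tic = TRUE,
                             apply_sqrt = FALSE)
  expect_equal(f1$x, f2$x, tolerance = 1e-12)
})

test_that("the cohort writer emits one dataset per TMA plus annotation,
           and round-trips exactly", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_tmas = 1, patients_per_tma = 2, axis_points = 120,
                    n_peaks = 5, n_effect = 2, spectra_per_core = c(2, 2),
                    seed = 37)
  co <- generate_cohort(cfg)
  files <- write_imzml(co, dir)
  expect_length(files$imzml, 1L)
  ann <- read_annotation(files$annotation)
  expect_length(unique(ann$patient_id), 2L)
  back <- read_imzml(files$imzml[1], tma_id = "tma01")
  expect_length(back, length(co$spectra))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$mz, co$spectra[[i]]$mz)
    expect_identical(back[[i]]$intensity, co$spectra[[i]]$intensity)
  }
})

test_that("per-class file splitting still reunifies into the same groups", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_tmas = 2, patients_per_tma = 2, axis_points = 100,
                    n_peaks = 5, n_effect = 1, spectra_per_core = c(2, 2),
                    seed = 39)
  co <- generate_cohort(cfg)
  files <- write_imzml(co, dir, split_by_class = TRUE)
  expect_length(files$imzml, 4L)  # 2 TMAs x 2 classes
  spectra <- unlist(lapply(files$imzml, function(p)
    read_imzml(p, tma_id = sub("_(pos|neg)$", "",
                               sub("\\.imzML$", "", basename(p))))),
    recursive = FALSE)
  groups <- assign_groups(spectra, read_annotation(files$annotation),
                          quiet = TRUE)
  direct <- assign_groups(co$spectra, co$annotation, quiet = TRUE)
  expect_setequal(vapply(groups, `[[`, character(1), "group_id"),
                  vapply(direct, `[[`, character(1), "group_id"))
})
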