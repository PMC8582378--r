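# Shared fixtures and independent oracles, all built in code.

# a plain spectrum with an evenly spaced axis
make_spectrum <- function(intensity, mz = NULL, coords = c(1L, 1L),
                          tma = "tmaA") {
  if (is.null(mz)) mz <- seq(100, 100 + length(intensity) - 1)
  msi_spectrum(mz, intensity, coords, tma)
}

# seeded random spectrum on a sorted random axis
random_spectrum <- function(n, mz_lo = 800, mz_hi = 1100,
                            coords = c(1L, 1L), tma = "tmaA") {
  mz <- sort(runif(n, mz_lo, mz_hi))
  while (any(diff(mz) == 0)) mz <- sort(runif(n, mz_lo, mz_hi))
  msi_spectrum(mz, rexp(n), coords, tma)
}

# lightweight tissue group carrying a single dummy spectrum (for split
# construction tests that never touch intensities)
stub_group <- function(group_id, patient_id, label, tma_id) {
  structure(
    list(group_id = group_id, patient_id = patient_id,
         label = as.integer(label), tma_id = tma_id,
         spectra = list(make_spectrum(c(1, 1), tma = tma_id))),
    class = "tissue_group")
}

# a roster of stub groups: one group per patient, `n_pos` positive and
# `n_neg` negative, spread over `n_tmas` TMAs
stub_cohort <- function(n_pos, n_neg, n_tmas = 3L) {
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  lapply(seq_along(labels), function(i) {
    stub_group(sprintf("G%03d", i), sprintf("P%03d", i), labels[i],
               sprintf("tma%02d", ((i - 1L) %% n_tmas) + 1L))
  })
}

# brute-force AUC: all positive-negative pairs, ties count one half
brute_auc <- function(y, conf) {
  pos <- conf[y == 1]
  neg <- conf[y == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# a small, quickly trainable cohort with strong class signal
quick_cohort <- function(seed = 3L, n_tmas = 2L, patients = 6L,
                         fold_change = 4) {
  cfg <- sim_config(n_tmas = n_tmas, patients_per_tma = patients,
                    axis_points = 400, mz_range = c(800, 890),
                    spectra_per_core = c(3L, 5L), n_peaks = 12L,
                    n_effect = 4L, fold_change = fold_change,
                    noise_sdlog = 0.2, seed = seed)
  co <- generate_cohort(cfg)
  groups <- assign_groups(co$spectra, co$annotation, quiet = TRUE)
  list(cohort = co, groups = groups)
}
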