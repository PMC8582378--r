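#' Configuration for a synthetic MALDI-MSI TMA cohort
#'
#' Defines a seeded generative model emulating the structure of tryptic
#' peptide imaging TMA cohorts: several TMAs whose m/z axes differ by a
#' small jitter at both extremes; patients carrying negative (e.g. normal)
#' and/or positive (e.g. tumour) tissue cores; spectra that are sums of
#' shared Gaussian peptide-like peaks whose mean amplitude decays with m/z
#' (low-mass bins carry far more signal); a configurable subset of
#' class-discriminating peaks scaled by a fold change in positive-class
#' cores; per-pixel log-normal multiplicative noise per peak plus a small
#' half-normal additive baseline.
#'
#' @param n_tmas number of TMAs.
#' @param patients_per_tma patients per TMA (all with both tissue classes);
#'   ignored when `patient_composition` is given.
#' @param patient_composition optional named cohort-wide counts
#'   `c(both = , pos_only = , neg_only = )` distributed round-robin over
#'   TMAs (e.g. the colorectal design `c(both = 262, pos_only = 16,
#'   neg_only = 24)` yields 564 tissue groups).
#' @param cores_per_patient named counts `c(neg = , pos = )` of tissue cores
#'   per class for a patient carrying that class (default 2 normal + 4
#'   tumour, the colorectal layout).
#' @param spectra_per_core inclusive integer range; each core's pixel count
#'   is drawn uniformly from it.
#' @param axis_points m/z points per spectrum.
#' @param mz_range global m/z interval in Da before per-TMA jitter.
#' @param axis_jitter amplitude (Da) of the uniform jitter applied to each
#'   TMA's axis extremes; keep it below half the bin width so harmonization
#'   absorbs it.
#' @param n_peaks shared peptide-like peaks, positions drawn uniformly over
#'   the interior of the m/z range subject to a minimum separation of
#'   4 peak sigmas.
#' @param peak_sigma Gaussian peak width (Da).
#' @param amp_decay e-folding scale (Da) of the amplitude decay with m/z.
#' @param amp_sdlog log-normal spread of per-peak base amplitudes.
#' @param n_effect number of class-discriminating peaks.
#' @param fold_change multiplier on discriminating-peak amplitude in
#'   positive-class cores (1 = no class signal).
#' @param effect_mz optional explicit discriminating peak centers (Da);
#'   must lie inside `mz_range`.
#' @param noise_sdlog per-pixel, per-peak log-normal noise scale.
#' @param baseline_sd additive half-normal baseline scale, relative to the
#'   mean base peak amplitude.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_tmas = 3L, patients_per_tma = 10L,
                       patient_composition = NULL,
                       cores_per_patient = c(neg = 2L, pos = 4L),
                       spectra_per_core = c(4L, 8L),
                       axis_points = 2000L, mz_range = c(800, 1100),
                       axis_jitter = 0.4, n_peaks = 40L, peak_sigma = 1.2,
                       amp_decay = 150, amp_sdlog = 0.5, n_effect = 10L,
                       fold_change = 3, effect_mz = NULL,
                       noise_sdlog = 0.3, baseline_sd = 0.02, seed = 1L) {
  stopifnot(n_tmas >= 1, axis_points >= 2, length(mz_range) == 2,
            mz_range[2] > mz_range[1], axis_jitter >= 0, n_peaks >= 1,
            peak_sigma > 0, fold_change > 0, n_effect >= 0,
            n_effect <= n_peaks, length(spectra_per_core) == 2,
            all(spectra_per_core >= 1),
            all(c("neg", "pos") %in% names(cores_per_patient)))
  if (!is.null(patient_composition)) {
    stopifnot(all(c("both", "pos_only", "neg_only") %in%
                    names(patient_composition)),
              sum(patient_composition) >= 1)
  }
  if (!is.null(effect_mz) &&
      (any(effect_mz <= mz_range[1]) || any(effect_mz >= mz_range[2]))) {
    stop("discriminating peak centers fall outside the m/z range")
  }
  structure(
    list(n_tmas = as.integer(n_tmas),
         patients_per_tma = as.integer(patients_per_tma),
         patient_composition = patient_composition,
         cores_per_patient = cores_per_patient,
         spectra_per_core = as.integer(spectra_per_core),
         axis_points = as.integer(axis_points), mz_range = mz_range,
         axis_jitter = axis_jitter, n_peaks = as.integer(n_peaks),
         peak_sigma = peak_sigma, amp_decay = amp_decay,
         amp_sdlog = amp_sdlog, n_effect = as.integer(n_effect),
         fold_change = fold_change, effect_mz = effect_mz,
         noise_sdlog = noise_sdlog, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

# uniform peak positions conditioned on a minimum separation: subtract the
# guaranteed gaps, draw order statistics, add the gaps back
draw_peak_positions <- function(n, lo, hi, min_sep) {
  slack <- (hi - lo) - (n - 1) * min_sep
  if (slack <= 0) stop("m/z range too narrow for ", n, " separated peaks")
  lo + sort(runif(n, 0, slack)) + (seq_len(n) - 1) * min_sep
}

#' Generate a synthetic cohort
#'
#' Deterministic given `cfg$seed`. Returns all spectra (one list over all
#' TMAs), an annotation table covering every pixel, the per-TMA axes, and
#' the ground-truth peak model (positions, base amplitudes, which peaks
#' discriminate), from which the noise-free class-mean spectrum on any axis
#' is `Phi %*% (amplitude * fold)`.
#'
#' @param cfg a [sim_config()].
#' @return Object of class `sim_cohort` with elements `spectra`,
#'   `annotation`, `axes` (named list per TMA), `peaks` (data.frame with
#'   `mz`, `amplitude`, `discriminating`), `effect`, `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    margin <- 3 * cfg$peak_sigma
    pos <- draw_peak_positions(cfg$n_peaks, cfg$mz_range[1] + margin,
                               cfg$mz_range[2] - margin,
                               4 * cfg$peak_sigma)
    amps <- exp(-(pos - cfg$mz_range[1]) / cfg$amp_decay) *
      stats::rlnorm(cfg$n_peaks, 0, cfg$amp_sdlog)
    disc <- rep(FALSE, cfg$n_peaks)
    if (cfg$n_effect > 0) {
      disc[sample.int(cfg$n_peaks, cfg$n_effect)] <- TRUE
    }
    if (!is.null(cfg$effect_mz)) {
      pos <- c(pos, cfg$effect_mz)
      amps <- c(amps, exp(-(cfg$effect_mz - cfg$mz_range[1]) /
                            cfg$amp_decay))
      disc <- c(disc, rep(TRUE, length(cfg$effect_mz)))
    }
    fold_pos <- ifelse(disc, cfg$fold_change, 1)
    bscale <- cfg$baseline_sd * mean(amps)

    # patient roster
    comp <- cfg$patient_composition
    if (is.null(comp)) {
      comp <- c(both = cfg$n_tmas * cfg$patients_per_tma,
                pos_only = 0L, neg_only = 0L)
    }
    kinds <- rep(c("both", "pos_only", "neg_only"),
                 times = comp[c("both", "pos_only", "neg_only")])
    n_pat <- length(kinds)
    pat_tma <- rep_len(seq_len(cfg$n_tmas), n_pat)

    spectra <- list()
    ann <- list()
    axes <- list()
    for (t in seq_len(cfg$n_tmas)) {
      tma <- sprintf("tma%02d", t)
      jit <- stats::runif(2, -cfg$axis_jitter, cfg$axis_jitter)
      axis <- seq(cfg$mz_range[1] + jit[1], cfg$mz_range[2] + jit[2],
                  length.out = cfg$axis_points)
      axes[[tma]] <- axis
      Phi <- exp(-outer(axis, pos, "-")^2 / (2 * cfg$peak_sigma^2))

      pats <- which(pat_tma == t)
      fac <- list(); meta <- list()
      for (p in pats) {
        pid <- sprintf("P%04d", p)
        classes <- switch(kinds[p], both = c(0L, 1L), pos_only = 1L,
                          neg_only = 0L)
        for (cl in classes) {
          gid <- paste0(pid, if (cl == 1L) "_pos" else "_neg")
          n_cores <- cfg$cores_per_patient[[if (cl == 1L) "pos" else "neg"]]
          for (core in seq_len(n_cores)) {
            n_spec <- sample(seq(cfg$spectra_per_core[1],
                                 cfg$spectra_per_core[2]), 1L)
            f <- (amps * if (cl == 1L) fold_pos else 1) *
              matrix(stats::rlnorm(length(pos) * n_spec, 0,
                                   cfg$noise_sdlog),
                     length(pos), n_spec)
            fac[[length(fac) + 1L]] <- f
            meta[[length(meta) + 1L]] <-
              data.frame(patient_id = pid, group_id = gid, label = cl,
                         n = n_spec, stringsAsFactors = FALSE)
          }
        }
      }
      if (length(fac) == 0L) next
      FF <- do.call(cbind, fac)
      intens <- Phi %*% FF +
        abs(matrix(stats::rnorm(length(axis) * ncol(FF), 0, bscale),
                   length(axis), ncol(FF)))
      md <- do.call(rbind, meta)
      n_pix <- ncol(FF)
      grid_w <- ceiling(sqrt(n_pix))
      xs <- ((seq_len(n_pix) - 1L) %% grid_w) + 1L
      ys <- ((seq_len(n_pix) - 1L) %/% grid_w) + 1L
      row_meta <- md[rep(seq_len(nrow(md)), md$n), ]
      for (j in seq_len(n_pix)) {
        spectra[[length(spectra) + 1L]] <-
          msi_spectrum(axis, intens[, j], c(xs[j], ys[j]), tma)
      }
      ann[[length(ann) + 1L]] <- data.frame(
        tma_id = tma, x = xs, y = ys,
        patient_id = row_meta$patient_id, group_id = row_meta$group_id,
        label = row_meta$label, stringsAsFactors = FALSE)
    }
    structure(
      list(spectra = spectra, annotation = do.call(rbind, ann),
           axes = axes,
           peaks = data.frame(mz = pos, amplitude = amps,
                              discriminating = disc),
           effect = list(peak_mz = pos[disc],
                         fold_change = cfg$fold_change),
           config = cfg),
      class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_cohort> %d spectra on %d TMAs; %d patients, %d groups; ",
           "%d peaks (%d discriminating, fold %.2g); seed %d\n"),
    length(x$spectra), length(x$axes),
    length(unique(x$annotation$patient_id)),
    length(unique(x$annotation$group_id)),
    nrow(x$peaks), sum(x$peaks$discriminating), x$effect$fold_change,
    x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk as imzML + annotation
#'
#' One continuous-mode imzML/ibd pair per TMA (or per TMA and class when
#' `split_by_class`, emulating cohorts stored in separate files for the two
#' tissue classes; pass the TMA id explicitly to [read_imzml()] to reunify
#' them) and a tab-delimited `annotation.tsv`. Everything the readers need
#' to round-trip the cohort exactly.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory, created if needed.
#' @param split_by_class write `<tma>_pos` / `<tma>_neg` file pairs.
#' @return Invisible list with `imzml` (paths) and `annotation` (path).
#' @export
write_imzml <- function(cohort, dir, split_by_class = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cohort$annotation
  key <- paste(ann$tma_id, ann$x, ann$y, sep = "\r")
  labels <- ann$label[match(
    vapply(cohort$spectra, function(s)
      paste(s$tma_id, s$coords[1], s$coords[2], sep = "\r"), character(1)),
    key)]
  paths <- character(0)
  for (tma in names(cohort$axes)) {
    in_tma <- vapply(cohort$spectra, function(s) s$tma_id == tma,
                     logical(1))
    if (split_by_class) {
      for (cl in c(0L, 1L)) {
        sel <- in_tma & labels == cl
        if (!any(sel)) next
        p <- file.path(dir, paste0(tma, if (cl == 1L) "_pos" else "_neg",
                                   ".imzML"))
        write_imzml_file(cohort$spectra[sel], p)
        paths <- c(paths, p)
      }
    } else {
      p <- file.path(dir, paste0(tma, ".imzML"))
      write_imzml_file(cohort$spectra[in_tma], p)
      paths <- c(paths, p)
    }
  }
  ann_path <- file.path(dir, "annotation.tsv")
  data.table::fwrite(ann, ann_path, sep = "\t")
  invisible(list(imzml = paths, annotation = ann_path))
}
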