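# Config-driven pipeline entry points. A run configuration is a YAML file
# (or an equivalent named list) with the defaults pre-filled to the
# standard analysis: bin width 3 Da, TIC normalization on, square root on,
# threshold 0.5.

default_run_config <- function() {
  list(seed = 1L, output_dir = ".", bin_width = 3, tic = TRUE,
       sqrt = TRUE, threshold = 0.5,
       cv = list(design = "loto", k = 10L, n_per_class = 10L),
       simulate = list(), input = list())
}

#' Load a run configuration
#'
#' @param config path to a YAML file or a named list; missing fields take
#'   the pre-filled defaults.
#' @return Merged configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out <- utils::modifyList(default_run_config(), config)
  if (out$threshold < 0 || out$threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  has_sim <- length(out$simulate) > 0
  has_input <- length(out$input) > 0
  if (has_sim && has_input) {
    stop("config must name exactly one input source (simulate or input)")
  }
  out
}

write_manifest <- function(dir, command, config, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(list(command = command, seed = config$seed,
           package_version = as.character(utils::packageVersion("msitma")),
           config = config), extra),
    file.path(dir, paste0(command, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Generate and write a synthetic cohort (pipeline command)
#'
#' @param config run configuration (see [read_run_config()]); the
#'   `simulate` block holds [sim_config()] fields, `seed` seeds the
#'   generator, `output_dir` receives the imzML files and annotation.
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  cfg <- do.call(sim_config, utils::modifyList(config$simulate,
                                               list(seed = config$seed)))
  cohort <- generate_cohort(cfg)
  files <- write_imzml(cohort, config$output_dir)
  write_manifest(config$output_dir, "simulate", config,
                 list(n_spectra = length(cohort$spectra),
                      n_groups = length(unique(
                        cohort$annotation$group_id))))
  message(sprintf("wrote %d imzML datasets and %s",
                  length(files$imzml), files$annotation))
  invisible(files)
}

resolve_inputs <- function(input) {
  paths <- input$imzml
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.imzML$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no imzML inputs configured")
  if (is.null(input$annotation)) stop("no annotation table configured")
  list(imzml = paths, annotation = input$annotation)
}

load_groups <- function(config) {
  io <- resolve_inputs(config$input)
  spectra <- unlist(lapply(io$imzml, read_imzml), recursive = FALSE)
  ann <- read_annotation(io$annotation)
  assign_groups(spectra, ann)
}

#' Read, bin and transform a cohort into a feature matrix (pipeline command)
#'
#' Reads the configured imzML datasets and annotation, aggregates tissue
#' groups, builds the shared bin grid and writes the feature matrix under
#' `output_dir/features`. Logs the bin count and the intensity-conservation
#' check on the first spectrum.
#'
#' @param config run configuration with an `input` block
#'   (`imzml`: files or a directory; `annotation`: table path).
#' @return The `msi_features` object, invisibly.
#' @export
run_featurize <- function(config) {
  config <- read_run_config(config)
  groups <- load_groups(config)
  fm <- build_feature_matrix(groups, width = config$bin_width,
                             tic = config$tic, apply_sqrt = config$sqrt)
  message(sprintf("bin grid: B = %d bins of width %g Da over [%.6f, %.6f]",
                  fm$bin_spec$n_bins, fm$bin_spec$width,
                  fm$bin_spec$global_min, fm$bin_spec$global_max))
  s1 <- groups[[1]]$spectra[[1]]
  if (config$tic) s1 <- tic_normalize(s1)
  v1 <- bin_spectrum(s1, fm$bin_spec)
  rel <- abs(sum(v1) - sum(s1$intensity)) / sum(s1$intensity)
  message(sprintf("conservation check (first spectrum): relative error %.2e",
                  rel))
  out <- file.path(config$output_dir, "features")
  write_feature_matrix(fm, out)
  write_manifest(config$output_dir, "featurize", config,
                 list(n_bins = fm$bin_spec$n_bins, n_spectra = nrow(fm$x)))
  invisible(fm)
}

#' Cross-validated evaluation of the ensemble (pipeline command)
#'
#' Full per-spectrum and per-tissue-group cross-validation on the
#' configured cohort; reports are written under `output_dir/report`.
#'
#' @param config run configuration; the `cv` block selects the design
#'   (`loto` or `balanced`) and its parameters.
#' @return The `msi_cv` result, invisibly.
#' @export
run_crossval <- function(config) {
  config <- read_run_config(config)
  groups <- load_groups(config)
  cv <- run_cross_validation(
    groups, design = config$cv$design, k = config$cv$k,
    n_per_class = config$cv$n_per_class, width = config$bin_width,
    tic = config$tic, apply_sqrt = config$sqrt,
    threshold = config$threshold, seed = config$seed)
  message("patient-leakage assertion passed for every split")
  print(cv)
  out <- file.path(config$output_dir, "report")
  write_cv_report(cv, out)
  write_manifest(config$output_dir, "crossval", config,
                 list(n_folds = nrow(cv$folds)))
  invisible(cv)
}
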