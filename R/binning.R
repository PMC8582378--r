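#' Build the shared m/z bin grid across datasets
#'
#' Different TMAs are acquired with slightly different m/z axes (different
#' point counts and extremes). To give every spectrum the same feature space,
#' a single linear bin grid is laid over the global m/z range of all
#' datasets: the bin count is the range divided by the bin width, rounded to
#' the nearest integer, and bin centers are equally spaced between the global
#' minimum and maximum inclusive.
#'
#' @param dataset_extremes two-column matrix or data.frame, one row per
#'   dataset, columns `(min m/z, max m/z)` in Da; or a numeric vector of
#'   length 2 for a single dataset.
#' @param width bin size in Da (default 3, with 6, 12 and 24 also sensible).
#' @return An object of class `bin_spec` with fields `width`, `global_min`,
#'   `global_max`, `n_bins` and `centers`.
#' @export
compute_bin_spec <- function(dataset_extremes, width = 3) {
  stopifnot(width > 0)
  if (is.numeric(dataset_extremes) && is.null(dim(dataset_extremes))) {
    dataset_extremes <- matrix(dataset_extremes, ncol = 2, byrow = TRUE)
  }
  dataset_extremes <- as.matrix(dataset_extremes)
  stopifnot(ncol(dataset_extremes) == 2, nrow(dataset_extremes) >= 1)
  gmin <- min(dataset_extremes[, 1])
  gmax <- max(dataset_extremes[, 2])
  if (gmax <= gmin) stop("degenerate m/z range: global max <= global min")
  B <- max(1L, as.integer(round((gmax - gmin) / width)))
  centers <- if (B == 1L) (gmin + gmax) / 2 else
    seq(gmin, gmax, length.out = B)
  structure(
    list(width = width, global_min = gmin, global_max = gmax,
         n_bins = B, centers = centers),
    class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf(
    "<bin_spec> %d bins of width %g Da over m/z [%.6f, %.6f]\n",
    x$n_bins, x$width, x$global_min, x$global_max))
  invisible(x)
}

# Nearest-center bin index for each m/z value; ties (exactly halfway between
# two centers) go to the lower-index bin, out-of-range points clamp to the
# end bins. Works on the equal spacing of the grid.
bin_assign <- function(mz, spec) {
  B <- spec$n_bins
  if (B == 1L) return(rep(1L, length(mz)))
  d <- (spec$global_max - spec$global_min) / (B - 1)
  t <- (mz - spec$centers[1]) / d
  idx <- as.integer(ceiling(t - 0.5))  # nearest, halfway rounds down
  pmin.env <- pmax(idx + 1L, 1L)
  pmin(pmin.env, B)
}

#' Bin one spectrum onto the shared grid
#'
#' Each m/z point is assigned to its nearest bin center and the intensities
#' of all points in a bin are summed, so the spectrum's total ion count is
#' conserved exactly (before any transform). Points outside the grid (from
#' per-TMA axis jitter) clamp to the nearest end bin.
#'
#' @param s an [msi_spectrum].
#' @param spec a [compute_bin_spec()] grid.
#' @return Numeric vector of length `spec$n_bins` with attribute
#'   `transformed = FALSE`.
#' @export
bin_spectrum <- function(s, spec) {
  stopifnot(inherits(s, "msi_spectrum"), inherits(spec, "bin_spec"))
  idx <- bin_assign(s$mz, spec)
  v <- numeric(spec$n_bins)
  if (length(idx)) {
    sums <- rowsum(s$intensity, idx)
    v[as.integer(rownames(sums))] <- sums[, 1]
  }
  attr(v, "transformed") <- FALSE
  v
}

#' Square-root dynamic-range reduction
#'
#' Binned intensities span several orders of magnitude, with far larger
#' values at low m/z; the elementwise square root compresses this dynamic
#' range so gradient-based learners converge faster. Monotone, so the
#' ordering of features within a spectrum is preserved.
#'
#' @param v non-negative numeric feature vector (or matrix, row per
#'   spectrum).
#' @return Same shape, square-rooted, with attribute `transformed = TRUE`.
#' @export
sqrt_transform <- function(v) {
  if (isTRUE(attr(v, "transformed"))) {
    stop("feature vector is already square-root transformed")
  }
  if (any(v < 0)) stop("negative feature values: upstream invariant violated")
  out <- sqrt(v)
  attr(out, "transformed") <- TRUE
  out
}

#' Build the learning feature matrix from tissue groups
#'
#' Flattens a cohort of tissue groups into one row per spectrum: optional TIC
#' normalization, binning onto a shared grid, and optional square-root
#' transform, with aligned label / group / patient / TMA bookkeeping vectors.
#' Each spectrum is treated as an independent sample; group identity is kept
#' for per-sample fusion and leakage-free cross-validation.
#'
#' @param groups list of `tissue_group` objects (see [assign_groups()]).
#' @param spec a [compute_bin_spec()] grid; if `NULL`, computed from the
#'   spectra's own extremes at `width`.
#' @param width bin width in Da used when `spec` is `NULL`.
#' @param tic apply [tic_normalize()] per spectrum before binning; spectra
#'   with zero total ion count are dropped with a message.
#' @param apply_sqrt apply [sqrt_transform()] to every row.
#' @return Object of class `msi_features`: list with matrix `x`
#'   (spectra x bins), integer `label`, character `group_id`, `patient_id`,
#'   `tma_id` (all per row), the `bin_spec`, and flags `tic`, `sqrt`.
#' @export
build_feature_matrix <- function(groups, spec = NULL, width = 3,
                                 tic = TRUE, apply_sqrt = TRUE) {
  if (length(groups) == 0L) stop("no tissue groups supplied")
  all_spectra <- unlist(lapply(groups, `[[`, "spectra"), recursive = FALSE)
  if (is.null(spec)) {
    ext <- t(vapply(groups, function(g) {
      rng <- range(unlist(lapply(g$spectra, function(s) range(s$mz))))
      rng
    }, numeric(2)))
    spec <- compute_bin_spec(ext, width = width)
  }
  n <- length(all_spectra)
  lab <- integer(n); gid <- character(n); pid <- character(n)
  tid <- character(n)
  i <- 0L
  for (g in groups) {
    for (s in g$spectra) {
      i <- i + 1L
      lab[i] <- g$label; gid[i] <- g$group_id
      pid[i] <- g$patient_id; tid[i] <- s$tma_id
    }
  }
  drop <- logical(n)
  x <- matrix(0, nrow = n, ncol = spec$n_bins)
  last_mz <- NULL; last_idx <- NULL
  for (j in seq_len(n)) {
    s <- all_spectra[[j]]
    if (tic) {
      tot <- sum(s$intensity)
      if (tot <= 0) { drop[j] <- TRUE; next }
      s$intensity <- s$intensity / tot
    }
    # axes repeat within a TMA; reuse the last assignment when unchanged
    if (is.null(last_mz) || !identical(s$mz, last_mz)) {
      last_mz <- s$mz
      last_idx <- bin_assign(s$mz, spec)
    }
    sums <- rowsum(s$intensity, last_idx)
    x[j, as.integer(rownames(sums))] <- sums[, 1]
  }
  if (any(drop)) {
    message(sum(drop), " empty (zero total ion count) spectra dropped")
    x <- x[!drop, , drop = FALSE]
    lab <- lab[!drop]; gid <- gid[!drop]; pid <- pid[!drop]; tid <- tid[!drop]
  }
  if (apply_sqrt) x <- sqrt(x)
  structure(
    list(x = x, label = lab, group_id = gid, patient_id = pid, tma_id = tid,
         bin_spec = spec, tic = tic, sqrt = apply_sqrt),
    class = "msi_features")
}

#' @export
print.msi_features <- function(x, ...) {
  cat(sprintf(
    paste0("<msi_features> %d spectra x %d bins (%d groups, %d patients, ",
           "%d TMAs); TIC %s, sqrt %s\n"),
    nrow(x$x), ncol(x$x), length(unique(x$group_id)),
    length(unique(x$patient_id)), length(unique(x$tma_id)),
    if (x$tic) "on" else "off", if (x$sqrt) "on" else "off"))
  invisible(x)
}

#' Persist a feature matrix as inspectable delimited text
#'
#' Writes three files under `dir`: `features.tsv` (one row per spectrum, one
#' column per bin), `metadata.tsv` (label, group_id, patient_id, tma_id per
#' row) and `manifest.json` (bin grid, flags, dimensions).
#'
#' @param fm an `msi_features` object.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fm, dir) {
  stopifnot(inherits(fm, "msi_features"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(fm$x), file.path(dir, "features.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.frame(label = fm$label, group_id = fm$group_id,
               patient_id = fm$patient_id, tma_id = fm$tma_id),
    file.path(dir, "metadata.tsv"), sep = "\t")
  jsonlite::write_json(
    list(n_spectra = nrow(fm$x), n_bins = ncol(fm$x),
         width = fm$bin_spec$width, global_min = fm$bin_spec$global_min,
         global_max = fm$bin_spec$global_max, tic = fm$tic, sqrt = fm$sqrt),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a feature matrix written by [write_feature_matrix()]
#' @param dir directory holding `features.tsv`, `metadata.tsv`,
#'   `manifest.json`.
#' @return An `msi_features` object.
#' @export
read_feature_matrix <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  x <- as.matrix(data.table::fread(file.path(dir, "features.tsv")))
  dimnames(x) <- NULL
  md <- as.data.frame(data.table::fread(file.path(dir, "metadata.tsv")))
  spec <- compute_bin_spec(c(man$global_min, man$global_max),
                           width = man$width)
  structure(
    list(x = x, label = as.integer(md$label),
         group_id = as.character(md$group_id),
         patient_id = as.character(md$patient_id),
         tma_id = as.character(md$tma_id),
         bin_spec = spec, tic = man$tic, sqrt = man$sqrt),
    class = "msi_features")
}
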