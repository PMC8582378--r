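#' Construct a single MALDI-MSI spectrum
#'
#' A spectrum is one pixel's mass spectrum: a strictly increasing m/z axis
#' (Da), non-negative intensities of the same length, integer pixel
#' coordinates, and the identity of the source dataset (typically one tissue
#' microarray, TMA).
#'
#' @param mz numeric vector of m/z values in Da, strictly increasing.
#' @param intensity numeric vector of non-negative ion counts, same length
#'   as `mz`.
#' @param coords integer vector `c(x, y)`, 1-based pixel position as in the
#'   imzML standard.
#' @param tma_id character scalar identifying the source dataset.
#' @return An object of class `msi_spectrum`.
#' @export
msi_spectrum <- function(mz, intensity, coords, tma_id) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  coords <- as.integer(coords)
  if (length(mz) != length(intensity)) {
    stop("m/z and intensity vectors differ in length (", length(mz), " vs ",
         length(intensity), ")")
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("m/z axis is not strictly increasing")
  }
  if (any(intensity < 0)) {
    stop("negative intensity values")
  }
  if (length(coords) != 2L || anyNA(coords)) {
    stop("coords must be an integer pair (x, y)")
  }
  structure(
    list(mz = mz, intensity = intensity, coords = coords,
         tma_id = as.character(tma_id)),
    class = "msi_spectrum"
  )
}

#' @export
print.msi_spectrum <- function(x, ...) {
  cat(sprintf(
    "<msi_spectrum> TMA %s pixel (%d, %d): %d m/z points in [%.4f, %.4f], TIC %.4g\n",
    x$tma_id, x$coords[1], x$coords[2], length(x$mz),
    if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA,
    sum(x$intensity)))
  invisible(x)
}

#' Total-ion-count normalization
#'
#' Scales a spectrum's intensities so that their sum (the total ion count)
#' equals `target` (default 1). The m/z axis is unchanged. TIC normalization
#' removes pixel-to-pixel variation in overall ion yield so spectra are
#' comparable; it is idempotent.
#'
#' @param s an [msi_spectrum].
#' @param target positive total the intensities should sum to after scaling.
#' @return The normalized `msi_spectrum`.
#' @export
tic_normalize <- function(s, target = 1) {
  stopifnot(inherits(s, "msi_spectrum"), target > 0)
  tic <- sum(s$intensity)
  if (tic <= 0) {
    stop("spectrum at pixel (", s$coords[1], ", ", s$coords[2],
         ") is empty (total ion count is zero)")
  }
  s$intensity <- s$intensity * (target / tic)
  s
}

#' Aggregate spectra into labelled patient tissue groups
#'
#' Matches each spectrum's `(tma_id, x, y)` against the annotation table and
#' collects all spectra of one tissue type from one patient into a tissue
#' group — the per-sample classification unit ("one tissue group is one
#' sample"). Spectra whose coordinates are not annotated are excluded and
#' counted; annotated coordinates with no matching spectrum are ignored.
#' Groups that would be empty are not emitted.
#'
#' @param spectra list of [msi_spectrum] objects.
#' @param ann annotation `data.frame` as returned by [read_annotation()]:
#'   columns `tma_id`, `x`, `y`, `patient_id`, `group_id`, `label`
#'   (0 = negative, 1 = positive).
#' @param quiet suppress the log message about excluded spectra.
#' @return A list of `tissue_group` objects, each with fields `group_id`,
#'   `patient_id`, `label`, `tma_id` and `spectra`; attribute `n_excluded`
#'   carries the count of unannotated spectra.
#' @export
assign_groups <- function(spectra, ann, quiet = FALSE) {
  ann <- validate_annotation(ann)
  if (length(spectra) == 0L) {
    res <- structure(list(), n_excluded = 0L)
    return(res)
  }
  keys <- vapply(spectra, function(s)
    paste(s$tma_id, s$coords[1], s$coords[2], sep = "\r"), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate spectrum coordinates within a TMA")
  }
  ann_keys <- paste(ann$tma_id, ann$x, ann$y, sep = "\r")
  idx <- match(keys, ann_keys)
  excluded <- sum(is.na(idx))
  if (!quiet) {
    message(excluded, " of ", length(spectra),
            " spectra not covered by the annotation; excluded")
  }
  keep <- which(!is.na(idx))
  if (length(keep) == 0L) {
    warning("annotation matches no spectrum coordinate; no groups emitted")
    return(structure(list(), n_excluded = excluded))
  }
  gid <- ann$group_id[idx[keep]]
  groups <- lapply(split(keep, gid), function(ii) {
    row <- ann[idx[ii[1]], ]
    structure(
      list(group_id = row$group_id, patient_id = row$patient_id,
           label = as.integer(row$label),
           tma_id = unique(vapply(spectra[ii], `[[`, character(1), "tma_id")),
           spectra = spectra[ii]),
      class = "tissue_group")
  })
  names(groups) <- NULL
  structure(groups, n_excluded = excluded)
}

#' @export
print.tissue_group <- function(x, ...) {
  cat(sprintf(
    "<tissue_group> %s (patient %s, label %d, TMA %s): %d spectra\n",
    x$group_id, x$patient_id, x$label, paste(x$tma_id, collapse = "+"),
    length(x$spectra)))
  invisible(x)
}

#' Read an annotation table
#'
#' The table maps pixels to patients, tissue groups and class labels. Two row
#' forms are accepted and may be mixed: per-pixel rows with columns `x`, `y`,
#' and rectangular-region shorthand rows with `x_min`, `x_max`, `y_min`,
#' `y_max` (inclusive bounds, expanded to pixels on read). Required columns:
#' `tma_id`, `patient_id`, `group_id`, `label` (0/1) plus one of the two
#' geometry forms.
#'
#' @param path delimited text file (tab or comma separated) with a header.
#' @return Validated per-pixel annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  ann <- as.data.frame(data.table::fread(path))
  validate_annotation(ann)
}

# Expand region shorthand, check the one-group-per-pixel and
# one-(patient,label)-per-group invariants.
validate_annotation <- function(ann) {
  need <- c("tma_id", "patient_id", "group_id", "label")
  if (!all(need %in% names(ann))) {
    stop("annotation lacks required columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  }
  has_xy <- all(c("x", "y") %in% names(ann))
  has_rect <- all(c("x_min", "x_max", "y_min", "y_max") %in% names(ann))
  if (!has_xy && !has_rect) {
    stop("annotation needs per-pixel columns x, y or region columns x_min..y_max")
  }
  if (has_rect) {
    rect_rows <- if (has_xy) is.na(ann$x) | is.na(ann$y) else
      rep(TRUE, nrow(ann))
    expand <- function(r) {
      g <- expand.grid(x = seq.int(r$x_min, r$x_max),
                       y = seq.int(r$y_min, r$y_max))
      data.frame(tma_id = r$tma_id, x = g$x, y = g$y,
                 patient_id = r$patient_id, group_id = r$group_id,
                 label = r$label, stringsAsFactors = FALSE)
    }
    px <- if (has_xy) ann[!rect_rows, c("tma_id", "x", "y", "patient_id",
                                        "group_id", "label")] else NULL
    rect <- ann[rect_rows, , drop = FALSE]
    ann <- do.call(rbind, c(list(px),
                            lapply(seq_len(nrow(rect)),
                                   function(i) expand(rect[i, ]))))
  } else {
    ann <- ann[, c("tma_id", "x", "y", "patient_id", "group_id", "label")]
  }
  ann$tma_id <- as.character(ann$tma_id)
  ann$patient_id <- as.character(ann$patient_id)
  ann$group_id <- as.character(ann$group_id)
  ann$label <- as.integer(ann$label)
  if (!all(ann$label %in% c(0L, 1L))) {
    stop("annotation labels must be 0 (negative) or 1 (positive)")
  }
  key <- paste(ann$tma_id, ann$x, ann$y, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup & ave(ann$group_id, key, FUN = function(g)
    length(unique(g)))[dup] != "1")) {
    bad <- ann[dup, ][1, ]
    stop("pixel (", bad$x, ", ", bad$y, ") on TMA ", bad$tma_id,
         " is claimed by more than one tissue group")
  }
  ann <- ann[!duplicated(key), ]
  per_group <- tapply(paste(ann$patient_id, ann$label, sep = "\r"),
                      ann$group_id, function(v) length(unique(v)))
  if (any(per_group != 1L)) {
    stop("tissue group ", names(per_group)[per_group != 1L][1],
         " maps to more than one (patient, label) pair")
  }
  rownames(ann) <- NULL
  ann
}
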