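# Cross-validation designs and the per-fold evaluation loop. Both designs
# split on tissue groups and guarantee that no patient contributes data to
# both sides of a split (the leakage assertion is always on).

group_table <- function(groups) {
  data.frame(
    group_id = vapply(groups, `[[`, character(1), "group_id"),
    patient_id = vapply(groups, `[[`, character(1), "patient_id"),
    label = vapply(groups, `[[`, integer(1), "label"),
    tma_id = vapply(groups, function(g) {
      if (length(g$tma_id) != 1L) {
        stop("group ", g$group_id, " spans more than one TMA")
      }
      g$tma_id
    }, character(1)),
    stringsAsFactors = FALSE)
}

new_split <- function(id, gt, val_ids) {
  val <- gt$group_id %in% val_ids
  val_patients <- unique(gt$patient_id[val])
  train <- !val & !(gt$patient_id %in% val_patients)
  structure(
    list(split_id = id,
         train_groups = gt$group_id[train],
         val_groups = gt$group_id[val],
         train_patients = unique(gt$patient_id[train]),
         val_patients = val_patients),
    class = "cv_split")
}

#' Leave-one-TMA-out cross-validation splits
#'
#' One split per TMA: all tissue groups on that TMA are validated, all
#' groups on the other TMAs train — simulating prediction on a newly
#' acquired array. Every group is validated exactly once. Because a patient
#' whose groups sat on two TMAs would leak between sides, that situation is
#' a fatal error.
#'
#' @param groups list of `tissue_group` objects.
#' @return List of `cv_split` objects, one per TMA, in TMA order.
#' @export
make_leave_one_tma_out_splits <- function(groups) {
  gt <- group_table(groups)
  if (length(unique(gt$tma_id)) < 2L) {
    stop("leave-one-TMA-out needs at least 2 distinct TMAs")
  }
  per_patient <- tapply(gt$tma_id, gt$patient_id,
                        function(v) length(unique(v)))
  if (any(per_patient > 1L)) {
    stop("patient ", names(per_patient)[per_patient > 1L][1],
         " has tissue groups on more than one TMA; ",
         "leave-one-TMA-out would leak patient data")
  }
  tmas <- sort(unique(gt$tma_id))
  splits <- lapply(seq_along(tmas), function(i)
    new_split(tmas[i], gt, gt$group_id[gt$tma_id == tmas[i]]))
  validate_splits(splits)
  splits
}

#' Balanced k-fold cross-validation splits
#'
#' Each of the `k` folds validates exactly `n_per_class` randomly chosen
#' tissue groups from each class (sampled without replacement within a
#' fold, independently across folds, so a scarce class may recur across
#' folds); the fold's training set is every group of every patient not in
#' that validation set. This is the design used when classes are too
#' unbalanced and too scattered across arrays for leave-one-TMA-out.
#'
#' @param groups list of `tissue_group` objects.
#' @param k number of folds.
#' @param n_per_class validation groups drawn from each class per fold.
#' @param seed integer seed making the draw reproducible.
#' @return List of `k` `cv_split` objects.
#' @export
make_balanced_folds <- function(groups, k = 10L, n_per_class = 10L,
                                seed = 1L) {
  gt <- group_table(groups)
  pos <- gt$group_id[gt$label == 1L]
  neg <- gt$group_id[gt$label == 0L]
  if (length(pos) < n_per_class || length(neg) < n_per_class) {
    stop("a class has fewer than n_per_class = ", n_per_class, " groups")
  }
  splits <- with_seed(seed, {
    lapply(seq_len(k), function(i) {
      val <- c(sample(pos, n_per_class), sample(neg, n_per_class))
      new_split(sprintf("fold%02d", i), gt, val)
    })
  })
  validate_splits(splits)
  splits
}

#' Assert that cross-validation splits cannot leak patient data
#'
#' Checks, for every split, that no group and no patient appears on both
#' the training and validation side. Called internally by every split
#' constructor and by [run_cross_validation()]; exported so reports and
#' tests can re-assert it.
#'
#' @param splits list of `cv_split` objects.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_splits <- function(splits) {
  for (s in splits) {
    if (length(intersect(s$train_groups, s$val_groups)) > 0L) {
      stop("split ", s$split_id, ": groups on both sides")
    }
    if (length(intersect(s$train_patients, s$val_patients)) > 0L) {
      stop("split ", s$split_id, ": patient on both sides (leakage)")
    }
  }
  invisible(TRUE)
}

#' Run a full cross-validated evaluation
#'
#' Builds the feature matrix once (shared bin grid over all TMAs), then for
#' every split trains the two-network ensemble on the training groups'
#' spectra, predicts the validation spectra, reports spectrum-level metrics,
#' fuses each validation group's confidences by their median, and reports
#' the fraction of groups classified correctly (overall and per class).
#' Fold metrics are aggregated as unweighted means across folds.
#'
#' @param groups list of `tissue_group` objects.
#' @param design `"loto"` (leave-one-TMA-out) or `"balanced"` (k-fold with
#'   class-balanced validation sets).
#' @param k,n_per_class balanced-design parameters.
#' @param width m/z bin width in Da.
#' @param tic,apply_sqrt preprocessing flags (see [build_feature_matrix()]).
#' @param threshold decision threshold.
#' @param seed integer seed driving fold construction and training.
#' @param members,mlp,conv forwarded to [fit_ensemble()].
#' @param verbose print progress per fold.
#' @return Object of class `msi_cv`: `folds` (per-fold metric table),
#'   `group_predictions` (per validated group: median confidence, predicted
#'   and true label), `aggregate` (mean over folds), plus the splits, bin
#'   grid and configuration.
#' @export
run_cross_validation <- function(groups, design = c("loto", "balanced"),
                                 k = 10L, n_per_class = 10L, width = 3,
                                 tic = TRUE, apply_sqrt = TRUE,
                                 threshold = 0.5, seed = 1L,
                                 members = c("mlp", "convnet"),
                                 mlp = NULL, conv = NULL, verbose = FALSE) {
  design <- match.arg(design)
  fm <- build_feature_matrix(groups, width = width, tic = tic,
                             apply_sqrt = apply_sqrt)
  splits <- switch(design,
    loto = make_leave_one_tma_out_splits(groups),
    balanced = make_balanced_folds(groups, k = k,
                                   n_per_class = n_per_class, seed = seed))
  fold_rows <- list()
  gp_rows <- list()
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    validate_splits(list(s))
    tr <- fm$group_id %in% s$train_groups
    va <- fm$group_id %in% s$val_groups
    if (verbose) {
      message(sprintf("split %s: %d training / %d validation spectra",
                      s$split_id, sum(tr), sum(va)))
    }
    ens <- fit_ensemble(fm$x[tr, , drop = FALSE], fm$label[tr],
                        seed = seed + i, mlp = mlp, conv = conv,
                        members = members, verbose = verbose)
    conf <- predict(ens, fm$x[va, , drop = FALSE])
    met <- compute_metrics(fm$label[va], conf, threshold)

    vg <- unique(fm$group_id[va])
    gp <- lapply(vg, function(g) {
      sel <- va & fm$group_id == g
      fu <- fuse_group(conf[fm$group_id[va] == g], threshold)
      data.frame(split_id = s$split_id, group_id = g,
                 true_label = fm$label[sel][1],
                 median_confidence = fu$median_confidence,
                 predicted = fu$predicted, stringsAsFactors = FALSE)
    })
    gp <- do.call(rbind, gp)
    correct <- gp$predicted == gp$true_label
    fold_rows[[i]] <- data.frame(
      split_id = s$split_id,
      n_train_spectra = sum(tr), n_val_spectra = sum(va),
      n_val_groups = nrow(gp),
      accuracy = met$accuracy, balanced_accuracy = met$balanced_accuracy,
      sensitivity = met$sensitivity, specificity = met$specificity,
      auc = met$auc,
      group_accuracy = mean(correct),
      group_accuracy_pos = if (any(gp$true_label == 1L))
        mean(correct[gp$true_label == 1L]) else NA_real_,
      group_accuracy_neg = if (any(gp$true_label == 0L))
        mean(correct[gp$true_label == 0L]) else NA_real_,
      stringsAsFactors = FALSE)
    gp_rows[[i]] <- gp
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- c("accuracy", "balanced_accuracy", "sensitivity",
                   "specificity", "auc", "group_accuracy",
                   "group_accuracy_pos", "group_accuracy_neg")
  aggregate <- as.list(colMeans(folds[, metric_cols], na.rm = TRUE))
  structure(
    list(folds = folds, group_predictions = do.call(rbind, gp_rows),
         aggregate = aggregate, splits = splits, design = design,
         threshold = threshold, seed = seed, bin_spec = fm$bin_spec,
         tic = tic, sqrt = apply_sqrt),
    class = "msi_cv")
}

#' @export
print.msi_cv <- function(x, ...) {
  cat(sprintf("<msi_cv> %s design, %d folds, threshold %.2f, seed %d\n",
              x$design, nrow(x$folds), x$threshold, x$seed))
  cat(sprintf(
    paste0("mean over folds: accuracy %.4f | balanced %.4f | AUC %.4f | ",
           "group accuracy %.4f\n"),
    x$aggregate$accuracy, x$aggregate$balanced_accuracy, x$aggregate$auc,
    x$aggregate$group_accuracy))
  invisible(x)
}

#' @export
summary.msi_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$folds, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Write cross-validation reports as delimited tables
#'
#' Emits `fold_metrics.tsv` (one row per split, Fig.-3/4-style overall and
#' per-class group accuracies included), `group_predictions.tsv` (one row
#' per validated tissue group) and `manifest.json` (design, seed, threshold,
#' bin grid).
#'
#' @param cv an `msi_cv` object.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  stopifnot(inherits(cv, "msi_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cv$folds, file.path(dir, "fold_metrics.tsv"),
                     sep = "\t")
  data.table::fwrite(cv$group_predictions,
                     file.path(dir, "group_predictions.tsv"), sep = "\t")
  jsonlite::write_json(
    list(design = cv$design, threshold = cv$threshold, seed = cv$seed,
         n_folds = nrow(cv$folds), aggregate = cv$aggregate,
         bin_spec = list(width = cv$bin_spec$width,
                         global_min = cv$bin_spec$global_min,
                         global_max = cv$bin_spec$global_max,
                         n_bins = cv$bin_spec$n_bins),
         tic = cv$tic, sqrt = cv$sqrt),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
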