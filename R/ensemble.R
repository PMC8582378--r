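#' Fit the two-network ensemble
#'
#' Trains the multilayer perceptron and the 1-D convolutional network on the
#' same rows and fuses them by averaging their sigmoid confidence outputs —
#' the configuration found to classify best. Seeds for the two members are
#' derived deterministically from `seed`.
#'
#' @param x feature matrix (spectra x bins) or an `msi_features` object.
#' @param y binary 0/1 labels (ignored when `x` is `msi_features`).
#' @param seed integer seed.
#' @param mlp,conv member specifications; defaults are the standard
#'   architectures ([mlp_spec()] sized to `ncol(x)`, [conv_spec()]).
#' @param members which members to train; both by default.
#' @param verbose print training progress.
#' @return Object of class `msi_ensemble`.
#' @export
fit_ensemble <- function(x, y = NULL, seed = 1L, mlp = NULL, conv = NULL,
                         members = c("mlp", "convnet"), verbose = FALSE) {
  if (inherits(x, "msi_features")) {
    y <- x$label
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(mlp)) mlp <- mlp_spec(ncol(x))
  if (is.null(conv)) conv <- conv_spec()
  members <- match.arg(members, several.ok = TRUE)
  fitted <- list()
  if ("mlp" %in% members) {
    fitted$mlp <- fit_mlp(x, y, spec = mlp, seed = seed, verbose = verbose)
  }
  if ("convnet" %in% members) {
    fitted$convnet <- fit_convnet(x, y, spec = conv, seed = seed + 1L,
                                  verbose = verbose)
  }
  structure(
    list(members = fitted, seed = seed, input_dim = ncol(x)),
    class = "msi_ensemble")
}

#' Per-spectrum ensemble confidences
#'
#' @param object an [fit_ensemble()] model.
#' @param newdata feature matrix or `msi_features` with the training column
#'   count.
#' @param ... unused.
#' @return Numeric vector of confidences in `[0, 1]`, the mean of the member
#'   outputs per row.
#' @export
predict.msi_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "msi_features")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim) {
    stop("newdata has ", ncol(newdata), " columns; ensemble was trained on ",
         object$input_dim)
  }
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' @export
print.msi_ensemble <- function(x, ...) {
  cat(sprintf("<msi_ensemble> members: %s; input length %d; seed %d\n",
              paste(names(x$members), collapse = " + "), x$input_dim,
              x$seed))
  for (m in x$members) print(m)
  invisible(x)
}

#' @export
summary.msi_ensemble <- function(object, ...) {
  cat("Two-network spectral classifier ensemble\n")
  print(object)
  for (nm in names(object$members)) {
    sp <- object$members[[nm]]$spec
    cat(sprintf("  %s: %s trainable parameters\n", nm,
                format(count_trainable_params(sp), big.mark = ",")))
  }
  invisible(object)
}
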