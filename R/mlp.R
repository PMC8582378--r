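# Dense network internals. Weights are plain matrices; all heavy lifting is
# BLAS matrix multiplication, so training the full 1024/512 architecture on
# desk-scale cohorts takes seconds.

add_bias <- function(A, b) A + rep(b, each = nrow(A))

#' Fit the multilayer perceptron
#'
#' Trains the dense classifier of [mlp_spec()] by mini-batch stochastic
#' gradient descent with momentum on the weighted binary cross-entropy,
#' following its two-phase learning-rate schedule exactly (no early
#' stopping). Weight initialization and epoch shuffling are driven by
#' `seed`, so a repeated run is bit-identical.
#'
#' @param x numeric matrix, one row per spectrum, `ncol(x)` must equal
#'   `spec$input_dim`.
#' @param y binary 0/1 vector, both classes present.
#' @param spec an [mlp_spec()]; defaults to the standard architecture sized
#'   to `ncol(x)`.
#' @param seed integer seed for initialization and shuffling.
#' @param init optional list of matrices `W` and vectors `b` to start from
#'   (used to verify permutation equivariance); layout as in the fitted
#'   object.
#' @param verbose print per-phase progress.
#' @return Object of class `msi_mlp` with elements `W`, `b`, `spec`,
#'   `seed`, `train_accuracy`.
#' @export
fit_mlp <- function(x, y, spec = mlp_spec(ncol(x)), seed = 1L, init = NULL,
                    verbose = FALSE) {
  x <- as.matrix(x); y <- as.numeric(y)
  check_training_input(x, y, spec$input_dim)
  dims <- c(spec$input_dim, spec$hidden, 1L)
  nl <- length(dims) - 1L

  with_seed(seed, {
    if (is.null(init)) {
      W <- lapply(seq_len(nl), function(l)
        matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
               dims[l], dims[l + 1L]))
      b <- lapply(seq_len(nl), function(l) numeric(dims[l + 1L]))
    } else {
      W <- init$W; b <- init$b
    }
    vW <- lapply(W, function(w) w * 0)
    vb <- lapply(b, function(v) v * 0)
    n <- nrow(x)
    w_sample <- ifelse(y == 1, spec$class_weight, 1)

    for (phase in seq_along(spec$epochs)) {
      lr <- spec$lr[phase]
      for (ep in seq_len(spec$epochs[phase])) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = spec$batch)) {
          ii <- ord[start:min(start + spec$batch - 1L, n)]
          m <- length(ii)
          X <- x[ii, , drop = FALSE]
          # forward
          A <- vector("list", nl); H <- vector("list", nl + 1L)
          H[[1]] <- X
          for (l in seq_len(nl)) {
            A[[l]] <- add_bias(H[[l]] %*% W[[l]], b[[l]])
            H[[l + 1L]] <- if (l < nl) pmax(A[[l]], 0) else A[[l]]
          }
          p <- plogis(A[[nl]])
          # backward (weighted BCE): dz = w * (p - y) / m
          delta <- (p - y[ii]) * w_sample[ii] / m
          for (l in rev(seq_len(nl))) {
            gW <- crossprod(H[[l]], delta)
            gb <- colSums(delta)
            if (l > 1L) {
              delta <- tcrossprod(delta, W[[l]])
              delta <- delta * (A[[l - 1L]] > 0)
            }
            vW[[l]] <- spec$momentum * vW[[l]] - lr * gW
            vb[[l]] <- spec$momentum * vb[[l]] - lr * gb
            W[[l]] <- W[[l]] + vW[[l]]
            b[[l]] <- b[[l]] + vb[[l]]
          }
        }
        if (verbose) {
          message(sprintf("mlp phase %d epoch %d (lr %g)", phase, ep, lr))
        }
      }
    }
  })

  model <- structure(
    list(W = W, b = b, spec = spec, seed = seed, train_accuracy = NA_real_),
    class = "msi_mlp")
  p_train <- predict(model, x)
  model$train_accuracy <- mean((p_train >= 0.5) == (y == 1))
  model
}

#' @export
predict.msi_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$spec$input_dim) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         object$spec$input_dim)
  }
  nl <- length(object$W)
  H <- X
  for (l in seq_len(nl)) {
    H <- add_bias(H %*% object$W[[l]], object$b[[l]])
    if (l < nl) H <- pmax(H, 0)
  }
  as.numeric(plogis(H))
}

#' @export
print.msi_mlp <- function(x, ...) {
  cat(sprintf(
    "<msi_mlp> input %d, hidden %s; training accuracy %.3f (seed %d)\n",
    x$spec$input_dim, paste(x$spec$hidden, collapse = "/"),
    x$train_accuracy, x$seed))
  invisible(x)
}

check_training_input <- function(x, y, input_dim) {
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  if (length(y) != nrow(x)) stop("labels and rows differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; loss is degenerate")
  }
  if (ncol(x) != input_dim) {
    stop("row length ", ncol(x), " does not match spec input_dim ", input_dim)
  }
  invisible(TRUE)
}
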