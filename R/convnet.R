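# 1-D convolutional network internals. Activations are held channel-first:
# a batch is a (C, L * N) matrix whose column (n - 1) * L + l is pixel n's
# position l. In this layout im2col is a column gather, batch normalization
# is row-recycled vector arithmetic, and every heavy step is one BLAS
# matrix multiplication. Kernels are (C_in * kernel, C_out) matrices with
# row (k - 1) * C_in + c.

conv1d_forward <- function(Xm, L, N, W, stride, kernel) {
  Cin <- nrow(Xm)
  Lout <- as.integer(ceiling(L / stride))
  pad <- max((Lout - 1L) * stride + kernel - L, 0L)
  pl <- pad %/% 2L
  Lp <- L + pad
  if (pad > 0L) {
    Xp <- matrix(0, Cin, Lp * N)
    cols <- rep((0:(N - 1L)) * Lp, each = L) + pl + seq_len(L)
    Xp[, cols] <- Xm
  } else {
    Xp <- Xm
  }
  patches <- matrix(0, Cin * kernel, Lout * N)
  base <- rep((0:(N - 1L)) * Lp, each = Lout) + (seq_len(Lout) - 1L) * stride
  for (k in seq_len(kernel)) {
    patches[(k - 1L) * Cin + seq_len(Cin), ] <- Xp[, base + k]
  }
  out <- crossprod(W, patches)  # (Cout, Lout * N)
  list(out = out, patches = patches, base = base, Cin = Cin, L = L, N = N,
       Lout = Lout, pl = pl, Lp = Lp, pad = pad, stride = stride,
       kernel = kernel)
}

conv1d_backward <- function(dY, cache, W) {
  dW <- tcrossprod(cache$patches, dY)  # (Cin * K, Cout)
  dpatch <- W %*% dY                      # (Cin * K, Lout * N)
  Cin <- cache$Cin
  dXp <- matrix(0, Cin, cache$Lp * cache$N)
  for (k in seq_len(cache$kernel)) {
    idx <- cache$base + k
    dXp[, idx] <- dXp[, idx] + dpatch[(k - 1L) * Cin + seq_len(Cin), ]
  }
  dX <- if (cache$pad > 0L) {
    cols <- rep((0:(cache$N - 1L)) * cache$Lp, each = cache$L) +
      cache$pl + seq_len(cache$L)
    dXp[, cols, drop = FALSE]
  } else dXp
  list(dW = dW, dX = dX)
}

BN_EPS <- 1e-3

bn_forward <- function(Xm, gamma, beta, run_mu, run_var, training,
                       rate = 0.1) {
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm * Xm) - mu * mu
    run_mu <- (1 - rate) * run_mu + rate * mu
    run_var <- (1 - rate) * run_var + rate * v
  } else {
    mu <- run_mu; v <- run_var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- (Xm - mu) * ivar      # length-C vectors recycle down columns
  list(out = xhat * gamma + beta, xhat = xhat, ivar = ivar,
       run_mu = run_mu, run_var = run_var)
}

bn_backward <- function(dY, cache, gamma) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$ivar
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

convnet_forward <- function(Xm, L, N, params, spec, training) {
  nl <- length(spec$filters)
  caches <- vector("list", nl)
  H <- Xm
  for (l in seq_len(nl)) {
    bn_c <- NULL; relu_mask <- NULL
    if (l %in% spec$bn_layers) {
      p <- params$bn[[l]]
      bn_c <- bn_forward(H, p$gamma, p$beta, p$run_mu, p$run_var, training)
      if (training) {
        params$bn[[l]]$run_mu <- bn_c$run_mu
        params$bn[[l]]$run_var <- bn_c$run_var
      }
      H <- bn_c$out
    }
    if (l >= 2L) {
      relu_mask <- H > 0
      H <- H * relu_mask
    }
    cv <- conv1d_forward(H, L, N, params$W[[l]], spec$strides[l],
                         spec$kernel)
    H <- cv$out
    L <- cv$Lout
    caches[[l]] <- list(bn = bn_c, relu = relu_mask, conv = cv)
  }
  z <- colMeans(matrix(H, L, N))  # global average pool (final C = 1)
  list(z = z, p = plogis(z), caches = caches, Lf = L, params = params)
}

convnet_backward <- function(dz, fw, params, spec) {
  nl <- length(spec$filters)
  grads <- list(W = vector("list", nl), bn = vector("list", nl))
  dH <- matrix(rep(dz, each = fw$Lf) / fw$Lf, 1L)
  for (l in rev(seq_len(nl))) {
    cc <- fw$caches[[l]]
    cb <- conv1d_backward(dH, cc$conv, params$W[[l]])
    grads$W[[l]] <- cb$dW
    dH <- cb$dX
    if (!is.null(cc$relu)) dH <- dH * cc$relu
    if (!is.null(cc$bn)) {
      bb <- bn_backward(dH, cc$bn, params$bn[[l]]$gamma)
      grads$bn[[l]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
      dH <- bb$dX
    }
  }
  grads
}

# rows of x (spectra) -> channel-first (1, B * n) matrix
rows_to_cf <- function(x) matrix(t(x), 1L)

#' Fit the one-dimensional convolutional network
#'
#' Trains the [conv_spec()] architecture by mini-batch SGD with momentum on
#' the (unweighted) binary cross-entropy, with per-layer weight decay on the
#' convolution kernels, following the three-phase learning-rate schedule
#' exactly (no early stopping). Batch-normalization running statistics are
#' accumulated during training and used at inference. Seeded, so repeated
#' runs are bit-identical.
#'
#' @param x numeric matrix, one row per spectrum (any number of columns —
#'   the architecture is length-agnostic).
#' @param y binary 0/1 vector, both classes present.
#' @param spec a [conv_spec()].
#' @param seed integer seed for initialization and shuffling.
#' @param verbose print per-phase progress.
#' @return Object of class `msi_convnet` with `params`, `spec`, `seed`,
#'   `train_accuracy`.
#' @export
fit_convnet <- function(x, y, spec = conv_spec(), seed = 1L,
                        verbose = FALSE) {
  x <- as.matrix(x); y <- as.numeric(y)
  check_training_input(x, y, ncol(x))
  nl <- length(spec$filters)
  in_ch <- c(1L, spec$filters[-nl])

  with_seed(seed, {
    params <- list(
      W = lapply(seq_len(nl), function(l) {
        fan_in <- in_ch[l] * spec$kernel
        matrix(rnorm(fan_in * spec$filters[l], sd = sqrt(2 / fan_in)),
               fan_in, spec$filters[l])
      }),
      bn = lapply(seq_len(nl), function(l) {
        if (!(l %in% spec$bn_layers)) return(NULL)
        list(gamma = rep(1, in_ch[l]), beta = rep(0, in_ch[l]),
             run_mu = rep(0, in_ch[l]), run_var = rep(1, in_ch[l]))
      }))
    vW <- lapply(params$W, function(w) w * 0)
    vbn <- lapply(params$bn, function(p) {
      if (is.null(p)) NULL else list(g = p$gamma * 0, b = p$beta * 0)
    })
    n <- nrow(x)

    for (phase in seq_along(spec$epochs)) {
      lr <- spec$lr[phase]
      for (ep in seq_len(spec$epochs[phase])) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = spec$batch)) {
          ii <- ord[start:min(start + spec$batch - 1L, n)]
          Xm <- rows_to_cf(x[ii, , drop = FALSE])
          fw <- convnet_forward(Xm, ncol(x), length(ii), params, spec,
                                training = TRUE)
          params <- fw$params  # running BN statistics were updated
          dz <- (fw$p - y[ii]) / length(ii)
          gr <- convnet_backward(dz, fw, params, spec)
          for (l in seq_len(nl)) {
            g <- gr$W[[l]] + spec$weight_decay * params$W[[l]]
            vW[[l]] <- spec$momentum * vW[[l]] - lr * g
            params$W[[l]] <- params$W[[l]] + vW[[l]]
            if (!is.null(params$bn[[l]])) {
              vbn[[l]]$g <- spec$momentum * vbn[[l]]$g -
                lr * gr$bn[[l]]$dgamma
              vbn[[l]]$b <- spec$momentum * vbn[[l]]$b -
                lr * gr$bn[[l]]$dbeta
              params$bn[[l]]$gamma <- params$bn[[l]]$gamma + vbn[[l]]$g
              params$bn[[l]]$beta <- params$bn[[l]]$beta + vbn[[l]]$b
            }
          }
        }
        if (verbose) {
          message(sprintf("convnet phase %d epoch %d (lr %g)", phase, ep,
                          lr))
        }
      }
    }
  })

  model <- structure(
    list(params = params, spec = spec, seed = seed,
         input_dim = ncol(x), train_accuracy = NA_real_),
    class = "msi_convnet")
  p_train <- predict(model, x)
  model$train_accuracy <- mean((p_train >= 0.5) == (y == 1))
  model
}

#' @export
predict.msi_convnet <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    stop("newdata has ", ncol(X), " columns; model was trained on ",
         object$input_dim)
  }
  n <- nrow(X)
  out <- numeric(n)
  # bound the im2col working set on large cohorts
  chunk <- max(1L, as.integer(2e6 / ncol(X)))
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    out[ii] <- convnet_forward(rows_to_cf(X[ii, , drop = FALSE]), ncol(X),
                               length(ii), object$params, object$spec,
                               training = FALSE)$p
  }
  out
}

#' @export
print.msi_convnet <- function(x, ...) {
  cat(sprintf(
    "<msi_convnet> %d conv layers, input length %d; training accuracy %.3f (seed %d)\n",
    length(x$spec$filters), x$input_dim, x$train_accuracy, x$seed))
  invisible(x)
}
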