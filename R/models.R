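#' Multilayer perceptron specification
#'
#' The dense classifier: two rectified-linear hidden layers of 1024 and 512
#' units (with biases) and a single sigmoid output, trained with binary
#' cross-entropy and stochastic gradient descent (batch 512, momentum 0.9),
#' 20 epochs at learning rate 0.01 then 10 at 0.001, with the positive class
#' weighted 2.5x in the loss to counter class imbalance. With 1232 input
#' bins this network has exactly 1,787,905 trainable parameters.
#'
#' @param input_dim number of input features (m/z bins).
#' @param hidden hidden layer sizes.
#' @param class_weight multiplier on the positive-class loss.
#' @param batch,momentum,epochs,lr training schedule; `epochs` and `lr` are
#'   parallel vectors of schedule phases.
#' @return Object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden = c(1024L, 512L), class_weight = 2.5,
                     batch = 512L, momentum = 0.9,
                     epochs = c(20L, 10L), lr = c(0.01, 0.001)) {
  stopifnot(input_dim >= 1, all(hidden >= 1),
            length(epochs) == length(lr))
  structure(
    list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
         class_weight = class_weight, batch = as.integer(batch),
         momentum = momentum, epochs = as.integer(epochs), lr = lr),
    class = "mlp_spec")
}

#' One-dimensional convolutional network specification
#'
#' The convolutional classifier: 12 one-dimensional convolution layers with
#' kernel 9 and no biases; strides 4 (layer 1), 3 (layers 6 and 10), else 1;
#' output filters (32,16,16,16,16,32,32,32,32,32,64,1). Layers 1-11 are
#' preceded by batch normalization (2 trainable parameters per input
#' channel), layers 2-12 additionally by a rectified-linear activation, and
#' the final feature map is reduced by global average pooling into a sigmoid
#' output. Trained with binary cross-entropy, SGD (batch 512, momentum 0.9,
#' weight decay 0.001 per convolution layer), 5 epochs at rate 0.1, 5 at
#' 0.01, 1 at 0.001, without class weighting. Has exactly 72,802 trainable
#' parameters regardless of the input length.
#'
#' @param kernel convolution kernel size.
#' @param filters output channels per layer.
#' @param strides stride per layer.
#' @param bn_layers indices of layers preceded by batch normalization.
#' @param batch,momentum,weight_decay,epochs,lr training schedule.
#' @return Object of class `conv_spec`.
#' @export
conv_spec <- function(kernel = 9L,
                      filters = c(32L, 16L, 16L, 16L, 16L, 32L, 32L, 32L,
                                  32L, 32L, 64L, 1L),
                      strides = c(4L, 1L, 1L, 1L, 1L, 3L, 1L, 1L, 1L, 3L,
                                  1L, 1L),
                      bn_layers = 1:11,
                      batch = 512L, momentum = 0.9, weight_decay = 0.001,
                      epochs = c(5L, 5L, 1L), lr = c(0.1, 0.01, 0.001)) {
  stopifnot(length(filters) == length(strides), length(epochs) == length(lr))
  structure(
    list(kernel = as.integer(kernel), filters = as.integer(filters),
         strides = as.integer(strides), bn_layers = as.integer(bn_layers),
         batch = as.integer(batch), momentum = momentum,
         weight_decay = weight_decay, epochs = as.integer(epochs), lr = lr),
    class = "conv_spec")
}

#' Count trainable parameters of a model specification
#'
#' Analytic enumeration: a dense layer contributes `in x out + out`
#' (weights + biases); a convolution layer `in_channels x out_channels x
#' kernel` (no biases); a batch-normalization layer `2 x in_channels`
#' (scale and shift; running statistics are not trainable).
#'
#' @param spec an [mlp_spec()] or [conv_spec()].
#' @return Integer parameter count.
#' @export
count_trainable_params <- function(spec) UseMethod("count_trainable_params")

#' @export
count_trainable_params.mlp_spec <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, 1L)
  total <- 0
  for (l in seq_len(length(dims) - 1L)) {
    total <- total + dims[l] * dims[l + 1L] + dims[l + 1L]
  }
  as.integer(total)
}

#' @export
count_trainable_params.conv_spec <- function(spec) {
  in_ch <- c(1L, spec$filters[-length(spec$filters)])
  conv <- sum(in_ch * spec$filters * spec$kernel)
  bn <- sum(2L * in_ch[spec$bn_layers])
  as.integer(conv + bn)
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat(sprintf(
    "<mlp_spec> %d -> %s -> 1 (sigmoid); %s trainable parameters\n",
    x$input_dim, paste(x$hidden, collapse = " -> "),
    format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.conv_spec <- function(x, ...) {
  cat(sprintf(
    "<conv_spec> %d conv layers (kernel %d, no biases), filters %s; %s trainable parameters\n",
    length(x$filters), x$kernel, paste(x$filters, collapse = ","),
    format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

#' Threshold confidences into binary class labels
#'
#' A confidence strictly smaller than the threshold is classified negative;
#' otherwise (confidence at or above the threshold) positive. The default
#' threshold is the standard 0.5 — no attempt is made to optimize it.
#'
#' @param confidences numeric vector in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`.
#' @return Integer vector of 0 (negative) / 1 (positive).
#' @export
classify <- function(confidences, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (any(confidences < 0 | confidences > 1)) {
    stop("confidences must lie in [0, 1]")
  }
  as.integer(confidences >= threshold)
}

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
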