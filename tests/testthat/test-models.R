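test_that("trainable-parameter counts match the analytic enumeration", {
  expect_identical(count_trainable_params(mlp_spec(1232)), 1787905L)
  expect_identical(count_trainable_params(conv_spec()), 72802L)
  # single dense layer 10 -> 1 with bias
  expect_identical(count_trainable_params(mlp_spec(10, hidden = integer(0))),
                   11L)
  # the conv count does not depend on any input length; normalizing before
  # all 12 layers instead of 11 would add 2 * 64 parameters
  expect_identical(count_trainable_params(conv_spec(bn_layers = 1:12)),
                   72930L)
})

test_that("thresholding follows the smaller-is-negative boundary rule", {
  expect_identical(classify(c(0.49, 0.50, 0.51), 0.5), c(0L, 1L, 1L))
  expect_identical(classify(rep(0, 4), 0.5), rep(0L, 4))
  expect_identical(classify(c(0.1, 0.9), 0), c(1L, 1L))
  expect_error(classify(c(0.5), 1.5), "threshold")
  expect_error(classify(c(-0.1), 0.5), "confidences")
})

test_that("training input contracts are enforced", {
  x <- matrix(rnorm(20), 2, 10)
  expect_error(fit_mlp(x[1, , drop = FALSE], 1, mlp_spec(10)), "at least 2")
  expect_error(fit_mlp(x, c(1, 1), mlp_spec(10)), "single class")
  expect_error(fit_mlp(x, c(0, 1), mlp_spec(12)), "input_dim")
})

make_separable <- function(n, b, shift = 3, seed = 31) {
  with_seed_ <- function(s, code) { set.seed(s); code }
  with_seed_(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(abs(rnorm(n * b, sd = 0.3)), n, b)
    x[y == 1L, seq(1, b, by = 4)] <- x[y == 1L, seq(1, b, by = 4)] + shift
    list(x = x, y = y)
  })
}

test_that("the perceptron separates a strongly shifted two-class matrix", {
  d <- make_separable(1500, 24)
  m <- fit_mlp(d$x, d$y, seed = 5)
  expect_gte(m$train_accuracy, 0.99)
  p <- predict(m, d$x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the conv net separates the same matrix", {
  d <- make_separable(1500, 24)
  m <- fit_convnet(d$x, d$y, seed = 6)
  expect_gte(m$train_accuracy, 0.99)
  p <- predict(m, d$x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("training is deterministic under a fixed seed", {
  d <- make_separable(300, 12)
  m1 <- fit_mlp(d$x, d$y, seed = 9)
  m2 <- fit_mlp(d$x, d$y, seed = 9)
  expect_identical(round(m1$train_accuracy, 3), round(m2$train_accuracy, 3))
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  c1 <- fit_convnet(d$x, d$y, seed = 9)
  c2 <- fit_convnet(d$x, d$y, seed = 9)
  expect_identical(predict(c1, d$x), predict(c2, d$x))
})

test_that("the perceptron has no spatial prior: feature permutation
           with matched initialization leaves predictions unchanged", {
  d <- make_separable(400, 16)
  spec <- mlp_spec(16)
  set.seed(77)
  dims <- c(16L, spec$hidden, 1L)
  init <- list(
    W = lapply(seq_len(3), function(l)
      matrix(rnorm(dims[l] * dims[l + 1], sd = 0.05), dims[l],
             dims[l + 1])),
    b = lapply(seq_len(3), function(l) numeric(dims[l + 1])))
  perm <- sample(16)
  init_perm <- init
  init_perm$W[[1]] <- init$W[[1]][perm, , drop = FALSE]
  m <- fit_mlp(d$x, d$y, spec, seed = 4, init = init)
  mp <- fit_mlp(d$x[, perm], d$y, spec, seed = 4, init = init_perm)
  expect_equal(predict(m, d$x), predict(mp, d$x[, perm]), tolerance = 1e-12)
})

test_that("randomly permuted labels yield chance-level held-out AUC", {
  d <- make_separable(900, 16)
  set.seed(55)
  y_perm <- sample(d$y)
  tr <- seq_len(600); va <- 601:900
  ens <- fit_ensemble(d$x[tr, ], y_perm[tr], seed = 8)
  conf <- predict(ens, d$x[va, ])
  auc <- compute_metrics(y_perm[va], pmin(pmax(conf, 0), 1))$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("ensemble confidences are member means, bounded by the members", {
  d <- make_separable(400, 12)
  ens <- fit_ensemble(d$x, d$y, seed = 10)
  p1 <- predict(ens$members$mlp, d$x)
  p2 <- predict(ens$members$convnet, d$x)
  pe <- predict(ens, d$x)
  expect_equal(pe, (p1 + p2) / 2, tolerance = 1e-15)
  expect_true(all(pe >= pmin(p1, p2) - 1e-12 & pe <= pmax(p1, p2) + 1e-12))
  expect_true(all(pe >= 0 & pe <= 1))
  expect_error(predict(ens, d$x[, 1:5]), "columns")
})

test_that("held-out separable spectra get higher positive confidences", {
  qc <- quick_cohort(seed = 19)
  fm <- build_feature_matrix(qc$groups, width = 3)
  tr <- fm$tma_id == "tma01"
  ens <- fit_ensemble(fm$x[tr, ], fm$label[tr], seed = 2)
  conf <- predict(ens, fm$x[!tr, ])
  expect_gt(mean(conf[fm$label[!tr] == 1]), mean(conf[fm$label[!tr] == 0]))
})

test_that("raising the threshold trades sensitivity for specificity
           monotonically", {
  set.seed(23)
  y <- rbinom(200, 1, 0.5)
  conf <- pmin(pmax(y * 0.3 + runif(200, 0, 0.7), 0), 1)
  prev_sens <- 1; prev_spec <- 0
  for (th in seq(0, 1, by = 0.1)) {
    m <- compute_metrics(y, conf, th)
    expect_lte(m$sensitivity, prev_sens + 1e-12)
    expect_gte(m$specificity, prev_spec - 1e-12)
    prev_sens <- m$sensitivity; prev_spec <- m$specificity
  }
})
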