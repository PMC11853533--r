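tiny_spec <- function(center_weight = 0.7, dropout = 0) {
  tcn_spec(input_shape = c(4, 10), filters = c(3, 3, 2), dilations = c(1, 2),
           dw_kernel = 2, pool = 2, dropout = dropout, n_classes = 3,
           center_weight = center_weight)
}

separable_set <- function(n, seed = 3) {
  set.seed(seed)
  tens <- vector("list", n)
  labs <- integer(n)
  for (i in seq_len(n)) {
    cl <- ((i - 1) %% 4) + 1
    m <- matrix(rnorm(4 * 10, 0, 0.3), 4, 10)
    m[cl, ] <- m[cl, ] + 2
    tens[[i]] <- m
    labs[i] <- cl
  }
  list(tensors = tens, labels = labs)
}

test_that("backpropagated gradients match finite differences", {
  spec <- tiny_spec()
  set.seed(2)
  x <- matrix(rnorm(40), 4, 10)
  y <- 2L
  par <- hybridbci:::tcn_init(spec, 5)
  centers <- matrix(rnorm(3 * spec$feature_dim), 3)
  lossfn <- function(p) {
    fw <- hybridbci:::tcn_forward_sample(p, spec, x)
    -log(fw$probs[y]) + 0.7 * 0.5 * sum((fw$feat - centers[y, ])^2)
  }
  fw <- hybridbci:::tcn_forward_sample(par, spec, x)
  dlog <- fw$probs; dlog[y] <- dlog[y] - 1
  g <- hybridbci:::tcn_backward_sample(par, spec, fw$cache, dlog,
                                       0.7 * (fw$feat - centers[y, ]))
  eps <- 1e-6
  probe <- list(
    list(\(p) p$dw_w[2, 1], \(p, v) { p$dw_w[2, 1] <- v; p }, g$dw_w[2, 1]),
    list(\(p) p$blocks[[1]][[1]]$W2[2, 1], \(p, v) { p$blocks[[1]][[1]]$W2[2, 1] <- v; p },
         g$blocks[[1]][[1]]$W2[2, 1]),
    list(\(p) p$blocks[[2]][[2]]$W2[1, 2], \(p, v) { p$blocks[[2]][[2]]$W2[1, 2] <- v; p },
         g$blocks[[2]][[2]]$W2[1, 2]),
    list(\(p) p$blocks[[3]][[1]]$W1[2, 3], \(p, v) { p$blocks[[3]][[1]]$W1[2, 3] <- v; p },
         g$blocks[[3]][[1]]$W1[2, 3]),
    list(\(p) p$fc_w[1, 4], \(p, v) { p$fc_w[1, 4] <- v; p }, g$fc_w[1, 4]))
  for (pr in probe) {
    num <- (lossfn(pr[[2]](par, pr[[1]](par) + eps)) -
              lossfn(pr[[2]](par, pr[[1]](par) - eps))) / (2 * eps)
    expect_equal(pr[[3]], num, tolerance = 1e-4)
  }
})

test_that("training fits separable data and is seed-deterministic", {
  d <- separable_set(200)
  spec <- tcn_spec(input_shape = c(4, 10), filters = c(8, 8, 4),
                   dilations = c(1, 2), dw_kernel = 2, pool = 2, dropout = 0,
                   n_classes = 4, batch_size = 16, lr = 0.01)
  m1 <- train_tcn(d$tensors, d$labels, spec, epochs = 10, seed = 9)
  expect_gte(utils::tail(m1$history$accuracy, 1), 0.95)
  expect_lt(utils::tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- train_tcn(d$tensors, d$labels, spec, epochs = 10, seed = 9)
  expect_equal(utils::tail(m1$history$loss, 1),
               utils::tail(m2$history$loss, 1), tolerance = 1e-6)
  # an overfit model reproduces its own training labels
  pred <- vapply(d$tensors[1:8], function(x) classify_plr(m1, x)$predicted_led, 0L)
  expect_equal(pred, d$labels[1:8])
})

test_that("zero center weight reduces the loss to plain cross-entropy", {
  d <- separable_set(40)
  spec0 <- tcn_spec(input_shape = c(4, 10), filters = c(4, 4, 2),
                    dilations = c(1, 2), dw_kernel = 2, pool = 2,
                    dropout = 0, n_classes = 4, batch_size = 8,
                    center_weight = 0)
  m <- train_tcn(d$tensors, d$labels, spec0, epochs = 2, seed = 1)
  expect_equal(m$history$loss, m$history$ce)
  spec7 <- tcn_spec(input_shape = c(4, 10), filters = c(4, 4, 2),
                    dilations = c(1, 2), dw_kernel = 2, pool = 2,
                    dropout = 0, n_classes = 4, batch_size = 8,
                    center_weight = 0.7)
  m7 <- train_tcn(d$tensors, d$labels, spec7, epochs = 2, seed = 1)
  expect_equal(m7$history$loss, m7$history$ce + 0.7 * m7$history$center)
})

test_that("class probabilities form a simplex for every forward pass", {
  d <- separable_set(20)
  spec <- tiny_spec()
  spec$n_classes <- 4
  m <- train_tcn(d$tensors, d$labels, spec, epochs = 1, seed = 2)
  for (x in d$tensors[1:10]) {
    p <- classify_plr(m, x)$probabilities
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  expect_error(classify_plr(list(), d$tensors[[1]]), "trained")
  expect_error(classify_plr(m, matrix(0, 3, 3)), "shape")
})

test_that("shape and input validation reject mismatched tensors", {
  d <- separable_set(8)
  spec <- tiny_spec()
  expect_error(train_tcn(d$tensors, rep(1L, 8), spec), "2 classes")
  expect_error(train_tcn(list(matrix(0, 5, 9)), c(1L, 2L), spec), "length")
  expect_error(train_tcn(list(matrix(0, 5, 9), matrix(0, 5, 9)),
                         c(1L, 2L), spec), "shape")
})
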