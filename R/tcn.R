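#' Temporal-convolutional-network architecture specification
#'
#' The four-class pupil-pattern classifier: a causal depthwise temporal
#' convolution over the input rows, three stacks of dilated causal
#' convolutions (kernel 2, dilations 1/2/4/8, ReLU), temporal max-pooling,
#' dropout, and a dense softmax head. Training minimizes sparse
#' cross-entropy plus `center_weight` times a center loss on the flattened
#' features before the softmax. With the defaults the flattened feature
#' dimension is 64 * floor(139/2) = 4416.
#'
#' @param input_shape `c(F, T)` input rows x time points (122 x 139 for the
#'   default binocular wavelet tensor).
#' @param filters filters of the three convolution stacks.
#' @param kernel temporal kernel size of the dilated convolutions.
#' @param dilations dilation ladder used inside every stack.
#' @param dw_kernel depthwise (input) kernel length.
#' @param pool max-pool size and stride over time.
#' @param dropout dropout rate on the flattened features (training only).
#' @param n_classes output classes.
#' @param lr Adam learning rate.
#' @param center_weight weight of the center-loss term.
#' @param center_alpha per-batch centroid update rate.
#' @param batch_size mini-batch size.
#' @return list of class `tcn_spec`; `$feature_dim` gives the flattened
#'   dimension.
#' @export
tcn_spec <- function(input_shape = c(122, 139), filters = c(512, 512, 64),
                     kernel = 2, dilations = c(1, 2, 4, 8), dw_kernel = 3,
                     pool = 2, dropout = 0.5, n_classes = 4, lr = 0.001,
                     center_weight = 0.7, center_alpha = 0.5,
                     batch_size = 32) {
  t_pool <- floor((input_shape[2] - pool) / pool) + 1
  spec <- list(input_shape = input_shape, filters = filters, kernel = kernel,
               dilations = dilations, dw_kernel = dw_kernel, pool = pool,
               dropout = dropout, n_classes = n_classes, lr = lr,
               center_weight = center_weight, center_alpha = center_alpha,
               batch_size = batch_size, t_pool = t_pool,
               feature_dim = filters[length(filters)] * t_pool)
  structure(spec, class = "tcn_spec")
}

shift_right <- function(m, d) {
  n <- ncol(m)
  if (d == 0) return(m)
  cbind(matrix(0, nrow(m), d), m[, seq_len(n - d), drop = FALSE])
}

shift_left_pad <- function(m, d) {
  n <- ncol(m)
  if (d == 0) return(m)
  cbind(m[, (d + 1):n, drop = FALSE], matrix(0, nrow(m), d))
}

tcn_init <- function(spec, seed = 1L) {
  set.seed(seed)
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  fdim <- spec$input_shape[1]
  par <- list(dw_w = he(fdim, spec$dw_kernel, spec$dw_kernel),
              dw_b = numeric(fdim), blocks = list())
  cin <- fdim
  for (b in seq_along(spec$filters)) {
    cout <- spec$filters[b]
    layers <- list()
    ci <- cin
    for (d in spec$dilations) {
      layers[[length(layers) + 1L]] <-
        list(W1 = he(cout, ci, ci * spec$kernel),
             W2 = he(cout, ci, ci * spec$kernel),
             b = numeric(cout), d = d)
      ci <- cout
    }
    par$blocks[[b]] <- layers
    cin <- cout
  }
  par$fc_w <- he(spec$n_classes, spec$feature_dim, spec$feature_dim)
  par$fc_b <- numeric(spec$n_classes)
  par
}

tcn_forward_sample <- function(par, spec, x, drop_mask = NULL) {
  if (!all(dim(x) == spec$input_shape)) {
    stop("input shape mismatch: expected ",
         paste(spec$input_shape, collapse = "x"), ", got ",
         paste(dim(x), collapse = "x"))
  }
  # depthwise causal conv + ReLU
  z <- matrix(par$dw_b, nrow(x), ncol(x))
  for (j in seq_len(spec$dw_kernel)) {
    z <- z + par$dw_w[, j] * shift_right(x, j - 1)
  }
  h <- pmax(z, 0)
  cache <- list(x = x, dw_z = z, blocks = list())
  for (b in seq_along(par$blocks)) {
    bl_cache <- list()
    for (l in seq_along(par$blocks[[b]])) {
      ly <- par$blocks[[b]][[l]]
      hs <- shift_right(h, ly$d)
      z <- ly$W1 %*% h + ly$W2 %*% hs + ly$b
      bl_cache[[l]] <- list(h_in = h, h_shift = hs, z = z)
      h <- pmax(z, 0)
    }
    cache$blocks[[b]] <- bl_cache
  }
  # max-pool over time
  t2 <- spec$t_pool
  i1 <- seq(1, by = spec$pool, length.out = t2)
  a1 <- h[, i1, drop = FALSE]
  a2 <- h[, i1 + 1, drop = FALSE]
  pool_mask <- a1 >= a2
  p <- pmax(a1, a2)
  feat <- as.numeric(p)
  cache$pool_mask <- pool_mask
  cache$h_last <- h
  cache$feat_raw <- feat
  if (!is.null(drop_mask)) feat <- feat * drop_mask
  cache$feat <- feat
  logits <- as.numeric(par$fc_w %*% feat + par$fc_b)
  m <- max(logits)
  probs <- exp(logits - m) / sum(exp(logits - m))
  list(logits = logits, probs = probs, feat = feat, cache = cache)
}

tcn_backward_sample <- function(par, spec, cache, dlogits, dfeat_extra = NULL,
                                drop_mask = NULL) {
  g <- list(dw_w = 0 * par$dw_w, dw_b = 0 * par$dw_b, blocks = list(),
            fc_w = dlogits %o% cache$feat, fc_b = dlogits)
  dfeat <- as.numeric(crossprod(par$fc_w, dlogits))
  if (!is.null(dfeat_extra)) dfeat <- dfeat + dfeat_extra
  if (!is.null(drop_mask)) dfeat <- dfeat * drop_mask
  cl <- spec$filters[length(spec$filters)]
  dp <- matrix(dfeat, cl, spec$t_pool)
  dh <- matrix(0, cl, ncol(cache$h_last))
  i1 <- seq(1, by = spec$pool, length.out = spec$t_pool)
  m <- cache$pool_mask
  for (tt in seq_len(spec$t_pool)) {
    tgt <- ifelse(m[, tt], i1[tt], i1[tt] + 1)
    dh[cbind(seq_len(cl), tgt)] <- dh[cbind(seq_len(cl), tgt)] + dp[, tt]
  }
  for (b in rev(seq_along(par$blocks))) {
    g$blocks[[b]] <- vector("list", length(par$blocks[[b]]))
    for (l in rev(seq_along(par$blocks[[b]]))) {
      ly <- par$blocks[[b]][[l]]
      cc <- cache$blocks[[b]][[l]]
      dz <- dh * (cc$z > 0)
      g$blocks[[b]][[l]] <- list(W1 = tcrossprod(dz, cc$h_in),
                                 W2 = tcrossprod(dz, cc$h_shift),
                                 b = rowSums(dz))
      dh <- crossprod(ly$W1, dz) + shift_left_pad(crossprod(ly$W2, dz), ly$d)
    }
  }
  dz <- dh * (cache$dw_z > 0)
  for (j in seq_len(spec$dw_kernel)) {
    g$dw_w[, j] <- rowSums(dz * shift_right(cache$x, j - 1))
  }
  g$dw_b <- rowSums(dz)
  g
}

grad_map2 <- function(a, b, f) {
  out <- list(dw_w = f(a$dw_w, b$dw_w), dw_b = f(a$dw_b, b$dw_b),
              blocks = list(), fc_w = f(a$fc_w, b$fc_w),
              fc_b = f(a$fc_b, b$fc_b))
  for (bb in seq_along(a$blocks)) {
    out$blocks[[bb]] <- lapply(seq_along(a$blocks[[bb]]), function(l) {
      al <- a$blocks[[bb]][[l]]; bl <- b$blocks[[bb]][[l]]
      r <- list(W1 = f(al$W1, bl$W1), W2 = f(al$W2, bl$W2), b = f(al$b, bl$b))
      if (!is.null(al$d)) r$d <- al$d
      r
    })
  }
  out
}

zero_like <- function(par) grad_map2(par, par, function(a, b) a * 0)

#' Train the pupil-pattern TCN
#'
#' Mini-batch Adam on cross-entropy plus `center_weight` x center loss
#' (0.5 mean squared distance of each flattened feature vector to its
#' class centroid; centroids updated after every batch at rate
#' `center_alpha`). Fully deterministic given `seed`.
#'
#' @param tensors list of feature matrices (see [cwt_features()]).
#' @param labels integer class labels 1..n_classes.
#' @param spec a [tcn_spec()].
#' @param epochs training epochs.
#' @param seed RNG seed (weights, shuffling, dropout).
#' @param verbose print per-epoch loss.
#' @param normalize_input rescale inputs by the training-set root mean
#'   square (wavelet power spans orders of magnitude); the factor is
#'   stored in the model and re-applied at prediction time.
#' @return list of class `tcn_model`: parameters, spec, centroids, and the
#'   per-epoch `history` (loss, cross-entropy, center term, accuracy).
#' @export
train_tcn <- function(tensors, labels, spec = tcn_spec(), epochs = 30,
                      seed = 1L, verbose = FALSE, normalize_input = TRUE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes to train")
  if (length(tensors) != length(labels)) stop("tensors/labels length mismatch")
  for (x in tensors) {
    if (!all(dim(x) == spec$input_shape)) {
      stop("tensor shape mismatch: expected ",
           paste(spec$input_shape, collapse = "x"), ", got ",
           paste(dim(x), collapse = "x"))
    }
  }
  input_scale <- 1
  if (normalize_input) {
    rms <- sqrt(mean(vapply(tensors, function(x) mean(unclass(x)^2),
                            numeric(1))))
    if (rms > 0) input_scale <- 1 / rms
    tensors <- lapply(tensors, function(x) unclass(x) * input_scale)
  }
  par <- tcn_init(spec, seed)
  centers <- matrix(0, spec$n_classes, spec$feature_dim)
  m_st <- zero_like(par)
  v_st <- zero_like(par)
  step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- length(tensors)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        ce = numeric(0), center = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_ce <- ep_ctr <- 0; ep_hit <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      bs <- length(idx)
      acc <- zero_like(par)
      batch_feats <- matrix(0, bs, spec$feature_dim)
      for (j in seq_along(idx)) {
        i <- idx[j]
        drop_mask <- if (spec$dropout > 0) {
          (stats::runif(spec$feature_dim) >= spec$dropout) / (1 - spec$dropout)
        } else NULL
        fw <- tcn_forward_sample(par, spec, tensors[[i]], drop_mask)
        y <- labels[i]
        batch_feats[j, ] <- fw$feat
        ep_ce <- ep_ce - log(max(fw$probs[y], 1e-12))
        diffc <- fw$feat - centers[y, ]
        ep_ctr <- ep_ctr + 0.5 * sum(diffc^2)
        ep_hit <- ep_hit + (which.max(fw$probs) == y)
        dlogits <- fw$probs
        dlogits[y] <- dlogits[y] - 1
        dfeat_extra <- spec$center_weight * diffc
        g <- tcn_backward_sample(par, spec, fw$cache, dlogits / bs,
                                 dfeat_extra / bs, drop_mask)
        acc <- grad_map2(acc, g, `+`)
      }
      step <- step + 1
      m_st <- grad_map2(m_st, acc, function(m, g) b1 * m + (1 - b1) * g)
      v_st <- grad_map2(v_st, acc, function(v, g) b2 * v + (1 - b2) * g^2)
      corr <- spec$lr * sqrt(1 - b2^step) / (1 - b1^step)
      upd <- grad_map2(m_st, v_st, function(m, v) corr * m / (sqrt(v) + eps))
      par <- grad_map2(par, upd, `-`)
      # center update from this batch's features
      for (k in unique(labels[idx])) {
        sel <- which(labels[idx] == k)
        delta <- colMeans(batch_feats[sel, , drop = FALSE]) - centers[k, ]
        centers[k, ] <- centers[k, ] + spec$center_alpha * delta
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_ce / n + spec$center_weight * ep_ctr / n,
      ce = ep_ce / n, center = ep_ctr / n, accuracy = ep_hit / n))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f\n", ep,
                  history$loss[ep], history$accuracy[ep]))
    }
  }
  structure(list(par = par, spec = spec, centers = centers,
                 input_scale = input_scale, history = history,
                 trained = TRUE),
            class = "tcn_model")
}

#' @export
print.tcn_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<tcn_model> %s -> %d classes; %d epochs, final loss %.4f, train acc %.3f\n",
              paste(x$spec$input_shape, collapse = "x"), x$spec$n_classes,
              h$epoch, h$loss, h$accuracy))
  invisible(x)
}

#' Classify one pupil feature tensor
#'
#' @param model a trained `tcn_model`.
#' @param tensor feature matrix matching the model's input shape.
#' @return list with `predicted_led` (argmax class) and `probabilities`
#'   (softmax vector summing to 1).
#' @export
classify_plr <- function(model, tensor) {
  if (!inherits(model, "tcn_model") || is.null(model$trained)) {
    stop("classify_plr needs a trained tcn_model")
  }
  fw <- tcn_forward_sample(model$par, model$spec,
                           unclass(tensor) * model$input_scale)
  list(predicted_led = which.max(fw$probs), probabilities = fw$probs)
}

#' Forward-pass shape contract of a TCN
#'
#' Runs one untrained forward pass and reports the flattened feature
#' dimension and output dimension, for asserting the architecture contract
#' (122 x 139 in, 4416 features, 4 outputs with the defaults).
#'
#' @param spec a [tcn_spec()].
#' @param seed init seed.
#' @return list with `input_shape`, `feature_dim`, `n_classes`.
#' @export
tcn_shapes <- function(spec = tcn_spec(), seed = 1L) {
  par <- tcn_init(spec, seed)
  x <- matrix(0.1, spec$input_shape[1], spec$input_shape[2])
  fw <- tcn_forward_sample(par, spec, x)
  list(input_shape = spec$input_shape, feature_dim = length(fw$feat),
       n_classes = length(fw$probs))
}
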