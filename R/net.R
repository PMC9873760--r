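#' Configuration of the convolutional rating network
#'
#' A small configurable convolutional network that maps an RGB image to a
#' liking rating. The head is a 10-way fully connected output normalized by a
#' softmax; the scalar readout is the probability-weighted average of 10
#' equally spaced bin centres spanning the rating range, so the prediction
#' always lies in \[0, 3\]. Training uses a Huber loss and stochastic gradient
#' descent with momentum 0.9, learning rate 1e-4 (decayed by 0.1 every 30
#' epochs), weight decay 5e-4 and batch size 100 by default. Inputs are scaled
#' so the longest edge matches `input_size` and zero-padded to a square canvas.
#'
#' @param input_size square canvas edge in pixels (desk-scale default 32).
#' @param conv_channels output channels per 3x3 convolution layer.
#' @param pool_after indices of conv layers followed by 2x2 max pooling.
#' @param fc_units hidden units of the two fully connected layers.
#' @param n_bins output bins (default 10).
#' @param value_range rating range spanned by the bin centres.
#' @param lr,momentum,weight_decay,batch_size,lr_decay,lr_decay_every SGD
#'   hyperparameters.
#' @param huber_delta Huber loss transition point.
#' @param trainable `"fc"` (default: convolution weights frozen, head
#'   fine-tuned) or `"all"`.
#' @return List of class `rating_net_config`.
#' @export
rating_net_config <- function(input_size = 32,
                              conv_channels = c(8, 16, 16, 32),
                              pool_after = seq_along(conv_channels),
                              fc_units = c(32, 32),
                              n_bins = 10, value_range = c(0, 3),
                              lr = 1e-4, momentum = 0.9,
                              weight_decay = 5e-4, batch_size = 100,
                              lr_decay = 0.1, lr_decay_every = 30,
                              huber_delta = 1, trainable = c("fc", "all")) {
  trainable <- match.arg(trainable)
  side <- input_size / 2^sum(pool_after <= length(conv_channels))
  stopifnot(side >= 1, input_size %% 2^length(pool_after) == 0)
  structure(list(input_size = input_size, conv_channels = conv_channels,
                 pool_after = pool_after, fc_units = fc_units,
                 n_bins = n_bins, value_range = value_range, lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = batch_size, lr_decay = lr_decay,
                 lr_decay_every = lr_decay_every, huber_delta = huber_delta,
                 trainable = trainable),
            class = "rating_net_config")
}

#' Reference 13-convolution + 2-FC configuration
#'
#' The VGG-16-shaped layer layout (13 convolutions with pooling after layers
#' 2, 4, 7, 10 and 13, then two fully connected layers), scaled down in width
#' so it is constructible and runnable on a desktop CPU. It exposes 15 ReLU
#' activation points.
#'
#' @param input_size canvas edge (default 64).
#' @param width_divisor channel-count divisor relative to the full-width
#'   layout (default 32).
#' @param ... further arguments to [rating_net_config()].
#' @export
reference_rating_net_config <- function(input_size = 64, width_divisor = 32,
                                        fc_units = pmax(8L, c(4096, 4096) %/%
                                                          (width_divisor * 4)),
                                        ...) {
  full <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
  rating_net_config(input_size = input_size,
                    conv_channels = pmax(2L, full %/% width_divisor),
                    pool_after = c(2, 4, 7, 10, 13),
                    fc_units = fc_units,
                    ...)
}

#' Initialize network weights
#' @param config a [rating_net_config()]
#' @param seed RNG seed (He-scaled Gaussian initialization)
#' @return Object of class `rating_net` (weights untrained).
#' @export
init_rating_net <- function(config, seed = 1L) {
  withr_seed(seed, {
    cin <- 3L
    conv <- list()
    side <- config$input_size
    for (l in seq_along(config$conv_channels)) {
      cout <- config$conv_channels[l]
      fan_in <- 9 * cin
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                   fan_in, cout),
        b = numeric(cout))
      cin <- cout
      if (l %in% config$pool_after) side <- side / 2L
    }
    flat <- as.integer(side * side * cin)
    dims <- c(flat, config$fc_units, config$n_bins)
    n_fc <- length(dims) - 1L
    fc <- lapply(seq_len(n_fc), function(l)
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1],
                                   sd = sqrt(2 / dims[l])),
                      dims[l], dims[l + 1]),
           # small positive bias on hidden layers guards against ReLU death
           b = rep(if (l < n_fc) 0.1 else 0, dims[l + 1])))
    structure(list(config = config, conv = conv, fc = fc,
                   bin_centers = seq(config$value_range[1],
                                     config$value_range[2],
                                     length.out = config$n_bins),
                   loss_log = numeric(0)),
              class = "rating_net")
  })
}

#' @export
print.rating_net <- function(x, ...) {
  cat(sprintf("<rating_net: %d conv + %d fc layers, input %dx%d, %s>\n",
              length(x$conv), length(x$fc), x$config$input_size,
              x$config$input_size,
              if (length(x$loss_log)) sprintf("trained %d epochs",
                                              length(x$loss_log))
              else "untrained"))
  invisible(x)
}

# -- preprocessing ------------------------------------------------------------

#' Scale-and-pad preprocessing to the network canvas
#'
#' Rescales the longest edge to `input_size` (nearest-neighbour) and fills the
#' remaining canvas with zero-valued (black) pixels.
#'
#' @param image a [raster_image()] or H x W x 3 array.
#' @param input_size canvas edge.
#' @return input_size x input_size x 3 array.
#' @export
preprocess_image <- function(image, input_size) {
  px <- if (inherits(image, "raster_image")) image$pixels else image
  h <- dim(px)[1]; w <- dim(px)[2]
  s <- input_size / max(h, w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  ri <- pmin(h, pmax(1L, round((seq_len(nh) - 0.5) / s + 0.5)))
  ci <- pmin(w, pmax(1L, round((seq_len(nw) - 0.5) / s + 0.5)))
  out <- array(0, c(input_size, input_size, 3))
  out[seq_len(nh), seq_len(nw), ] <- px[ri, ci, ]
  out
}

# -- forward / backward -------------------------------------------------------

# im2col for 3x3 stride-1 pad-1 convolution: x is H x W x C,
# result (H*W) x (9*C) with column blocks ordered by input channel.
im2col3 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  xp <- array(0, c(h + 2L, w + 2L, cc))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  out <- matrix(0, h * w, 9L * cc)
  k <- 0L
  for (ch in seq_len(cc)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    out[, k] <- xp[dy + seq_len(h), dx + seq_len(w), ch]
  }
  out
}

# adjoint of im2col3: fold a (H*W) x (9*C) gradient back to H x W x C
col2im3 <- function(g, h, w, cc) {
  gp <- array(0, c(h + 2L, w + 2L, cc))
  k <- 0L
  for (ch in seq_len(cc)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    gp[dy + seq_len(h), dx + seq_len(w), ch] <-
      gp[dy + seq_len(h), dx + seq_len(w), ch] + matrix(g[, k], h, w)
  }
  gp[2:(h + 1), 2:(w + 1), , drop = FALSE]
}

# 2x2 max pooling; returns pooled array and the argmax code (1..4) per cell
pool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  o <- seq(1, h, 2); e <- seq(2, h, 2)
  oc <- seq(1, w, 2); ec <- seq(2, w, 2)
  cand <- array(0, c(h / 2, w / 2, cc, 4))
  cand[, , , 1] <- x[o, oc, , drop = FALSE]
  cand[, , , 2] <- x[e, oc, , drop = FALSE]
  cand[, , , 3] <- x[o, ec, , drop = FALSE]
  cand[, , , 4] <- x[e, ec, , drop = FALSE]
  am <- apply(cand, 1:3, which.max)
  mx <- apply(cand, 1:3, max)
  list(x = mx, argmax = am)
}

unpool2 <- function(g, argmax, h, w) {
  cc <- dim(g)[3]
  out <- array(0, c(h, w, cc))
  o <- seq(1, h, 2); e <- seq(2, h, 2)
  oc <- seq(1, w, 2); ec <- seq(2, w, 2)
  out[o, oc, ] <- g * (argmax == 1)
  out[e, oc, ] <- out[e, oc, ] + g * (argmax == 2)
  out[o, ec, ] <- out[o, ec, ] + g * (argmax == 3)
  out[e, ec, ] <- out[e, ec, ] + g * (argmax == 4)
  out
}

# Full forward pass for one preprocessed image. Returns the readout, the
# post-ReLU activations of every layer, and (optionally) the caches needed for
# backpropagation.
net_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$config
  relu_acts <- list()
  cache <- if (keep_cache) list(conv = list(), fc = list()) else NULL
  conv_part <- net_forward_conv(net, x, keep_cache)
  fc_part <- net_forward_fc(net, conv_part$hvec, keep_cache)
  if (keep_cache) cache <- list(conv = conv_part$cache, fc = fc_part$cache)
  list(value = fc_part$value, p = fc_part$p,
       relu = c(conv_part$relu, fc_part$relu), cache = cache,
       conv_out_dim = conv_part$out_dim)
}

# convolutional stack only: returns the flattened output and per-layer caches
net_forward_conv <- function(net, x, keep_cache = FALSE) {
  cfg <- net$config
  relu_acts <- list()
  cache <- if (keep_cache) list() else NULL
  for (l in seq_along(net$conv)) {
    M <- im2col3(x)
    Z <- sweep(M %*% net$conv[[l]]$W, 2, net$conv[[l]]$b, "+")
    A <- pmax(Z, 0)
    h <- dim(x)[1]; w <- dim(x)[2]
    a_arr <- array(A, c(h, w, ncol(A)))
    relu_acts[[length(relu_acts) + 1L]] <- as.numeric(A)
    pooled <- NULL
    if (l %in% cfg$pool_after) {
      pooled <- pool2(a_arr)
      x_next <- pooled$x
    } else x_next <- a_arr
    if (keep_cache)
      cache[[l]] <- list(M = M, mask = Z > 0, h = h, w = w,
                         argmax = if (!is.null(pooled)) pooled$argmax,
                         in_dim = dim(x))
    x <- x_next
  }
  list(hvec = as.numeric(x), relu = relu_acts, cache = cache,
       out_dim = dim(x))
}

# fully connected head only (takes the flattened conv output)
net_forward_fc <- function(net, hvec, keep_cache = FALSE) {
  relu_acts <- list()
  cache <- if (keep_cache) list() else NULL
  n_fc <- length(net$fc)
  for (l in seq_len(n_fc)) {
    z <- as.numeric(crossprod(net$fc[[l]]$W, hvec)) + net$fc[[l]]$b
    if (l < n_fc) {
      a <- pmax(z, 0)
      relu_acts[[length(relu_acts) + 1L]] <- a
      if (keep_cache) cache[[l]] <- list(h_in = hvec, mask = z > 0)
      hvec <- a
    } else {
      if (keep_cache) cache[[l]] <- list(h_in = hvec)
      z_out <- z
    }
  }
  p <- exp(z_out - max(z_out))
  p <- p / sum(p)
  list(value = sum(p * net$bin_centers), p = p, relu = relu_acts,
       cache = cache)
}

# Backward pass: gradient of the Huber loss at one example.
net_backward <- function(net, fw, y) {
  cfg <- net$config
  e <- fw$value - y
  dL_dv <- if (abs(e) <= cfg$huber_delta) e else cfg$huber_delta * sign(e)
  dz <- dL_dv * fw$p * (net$bin_centers - fw$value)   # softmax readout grad

  n_fc <- length(net$fc)
  g_fc <- vector("list", n_fc)
  for (l in rev(seq_len(n_fc))) {
    cc <- fw$cache$fc[[l]]
    g_fc[[l]] <- list(W = outer(cc$h_in, dz), b = dz)
    dh <- as.numeric(net$fc[[l]]$W %*% dz)
    if (l > 1) dz <- dh * fw$cache$fc[[l - 1]]$mask
  }
  if (cfg$trainable == "fc")
    return(list(fc = g_fc, conv = NULL))

  g <- array(dh, fw$conv_out_dim)
  g_conv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    cc <- fw$cache$conv[[l]]
    if (l %in% cfg$pool_after) g <- unpool2(g, cc$argmax, cc$h, cc$w)
    Gz <- matrix(g, cc$h * cc$w, dim(g)[3]) * cc$mask
    g_conv[[l]] <- list(W = crossprod(cc$M, Gz), b = colSums(Gz))
    if (l > 1) {
      gcol <- Gz %*% t(net$conv[[l]]$W)
      g <- col2im3(gcol, cc$in_dim[1], cc$in_dim[2], cc$in_dim[3])
    }
  }
  list(fc = g_fc, conv = g_conv)
}

#' Train the rating network
#'
#' Stochastic gradient descent with momentum on the Huber loss between the
#' network's scalar readout and the ratings. By default only the fully
#' connected layers are trained (the convolutional features are frozen). An
#' optional stopping criterion halts training once the correlation between the
#' network's predictions and the training ratings reaches a benchmark value
#' (e.g. a cross-validated accuracy estimated beforehand).
#'
#' @param images list of [raster_image()] (or arrays); preprocessed internally.
#' @param ratings numeric ratings on the network's value range.
#' @param config a [rating_net_config()].
#' @param epochs maximum training epochs.
#' @param stop_at_correlation optional early-stop benchmark.
#' @param seed seed for initialization and batch shuffling.
#' @return A trained `rating_net` with `loss_log` (mean Huber loss per epoch)
#'   and `train_correlation`.
#' @export
train_rating_net <- function(images, ratings, config = rating_net_config(),
                             epochs = 30, stop_at_correlation = NULL,
                             seed = 1L) {
  stopifnot(length(images) == length(ratings))
  net <- init_rating_net(config, seed)
  xs <- lapply(images, preprocess_image, input_size = config$input_size)
  n <- length(xs)
  fc_only <- config$trainable == "fc"
  # frozen convolutions: run the conv stack once per image and train the
  # head on the cached features
  hcache <- if (fc_only) lapply(xs, function(x) net_forward_conv(net, x)$hvec)
  fwd <- function(i, keep_cache = FALSE) {
    if (fc_only) {
      r <- net_forward_fc(net, hcache[[i]], keep_cache)
      list(value = r$value, p = r$p, cache = list(fc = r$cache))
    } else net_forward(net, xs[[i]], keep_cache)
  }

  vel <- list(fc = lapply(net$fc, function(l)
                list(W = l$W * 0, b = l$b * 0)),
              conv = lapply(net$conv, function(l)
                list(W = l$W * 0, b = l$b * 0)))
  lr <- config$lr
  huber <- function(e) ifelse(abs(e) <= config$huber_delta, 0.5 * e^2,
                              config$huber_delta * (abs(e) -
                                                      0.5 * config$huber_delta))
  withr_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      if (ep > 1 && (ep - 1) %% config$lr_decay_every == 0)
        lr <- lr * config$lr_decay
      ord <- sample(n)
      losses <- numeric(0)
      for (b0 in seq(1, n, by = config$batch_size)) {
        bidx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        acc <- NULL
        for (i in bidx) {
          fw <- fwd(i, keep_cache = TRUE)
          losses <- c(losses, huber(fw$value - ratings[i]))
          g <- net_backward(net, fw, ratings[i])
          acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
        }
        net <- sgd_step(net, acc, vel, lr, length(bidx))
        vel <- attr(net, "velocity")
        attr(net, "velocity") <- NULL
      }
      net$loss_log <- c(net$loss_log, mean(losses))
      if (!is.null(stop_at_correlation)) {
        preds <- vapply(seq_len(n), function(i) fwd(i)$value, numeric(1))
        if (stats::sd(preds) > 0 &&
            stats::cor(preds, ratings) >= stop_at_correlation) break
      }
    }
  })
  preds <- vapply(seq_len(n), function(i) fwd(i)$value, numeric(1))
  net$train_correlation <- if (stats::sd(preds) > 0)
    stats::cor(preds, ratings) else NA_real_
  net
}

accumulate_grads <- function(a, g) {
  add <- function(u, v) if (is.null(u)) NULL else
    Map(function(x, y) list(W = x$W + y$W, b = x$b + y$b), u, v)
  list(fc = add(a$fc, g$fc), conv = add(a$conv, g$conv))
}

sgd_step <- function(net, grads, vel, lr, batch_n) {
  cfg <- net$config
  upd <- function(layers, gs, vs) {
    for (l in seq_along(gs)) {
      if (is.null(gs[[l]])) next
      gW <- gs[[l]]$W / batch_n + cfg$weight_decay * layers[[l]]$W
      gb <- gs[[l]]$b / batch_n
      vs[[l]]$W <- cfg$momentum * vs[[l]]$W + gW
      vs[[l]]$b <- cfg$momentum * vs[[l]]$b + gb
      layers[[l]]$W <- layers[[l]]$W - lr * vs[[l]]$W
      layers[[l]]$b <- layers[[l]]$b - lr * vs[[l]]$b
    }
    list(layers = layers, vel = vs)
  }
  r1 <- upd(net$fc, grads$fc, vel$fc)
  net$fc <- r1$layers; vel$fc <- r1$vel
  if (!is.null(grads$conv)) {
    r2 <- upd(net$conv, grads$conv, vel$conv)
    net$conv <- r2$layers; vel$conv <- r2$vel
  }
  attr(net, "velocity") <- vel
  net
}

#' Predict ratings for a set of images
#' @param net a `rating_net`
#' @param images list of images
#' @return numeric readouts (always within the configured value range).
#' @export
predict_rating <- function(net, images) {
  vapply(images, function(im)
    net_forward(net, preprocess_image(im, net$config$input_size))$value,
    numeric(1))
}

#' Post-ReLU activations of every layer for a set of images
#'
#' @param net a `rating_net` (trained or untrained; the untrained net is the
#'   random-weights control).
#' @param images list of images.
#' @return Object of class `layer_activations`: list with one stimuli x units
#'   matrix per ReLU point (convolution layers first, then the hidden fully
#'   connected layers).
#' @export
layer_activations <- function(net, images) {
  xs <- lapply(images, preprocess_image, input_size = net$config$input_size)
  per_img <- lapply(xs, function(x) net_forward(net, x)$relu)
  n_layers <- length(per_img[[1]])
  out <- lapply(seq_len(n_layers), function(l)
    do.call(rbind, lapply(per_img, `[[`, l)))
  names(out) <- c(paste0("conv", seq_along(net$conv)),
                  paste0("fc", seq_len(length(net$fc) - 1L)))
  structure(out, class = "layer_activations")
}

#' @export
print.layer_activations <- function(x, ...) {
  cat(sprintf("<layer_activations: %d layers, %d stimuli>\n", length(x),
              nrow(x[[1]])))
  invisible(x)
}
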