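# Minimal sequential neural-network engine: 1 x k convolutions over
# (batch, channel, time, feature) tensors, 1 x 2 max pooling, dense layers,
# inverted dropout, ReLU / sigmoid / softmax, Adam, and binary or categorical
# cross-entropy. Heavy tensor ops live in src/pnesnet.cpp; everything is
# seeded through R's RNG so fits are bit-reproducible.

glorot_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# "same" padding arithmetic (floor-left convention).
conv_same_geometry <- function(t_in, k, stride) {
  t_out <- ceiling(t_in / stride)
  pad_total <- max((t_out - 1L) * stride + k - t_in, 0L)
  list(t_out = as.integer(t_out), pad_left = as.integer(pad_total %/% 2))
}

# Initialise parameters and static shape information for a layer stack.
# input_shape: c(H, T, C) for tensor input or a single integer for flat input.
nn_init <- function(layers, input_shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shape <- input_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv1x") {
      stopifnot(length(shape) == 3)
      geo <- conv_same_geometry(shape[2], ly$k, ly$stride)
      cin <- shape[3]
      ly$pad_left <- geo$pad_left
      ly$t_out <- geo$t_out
      ly$W <- array(glorot_uniform(ly$k * cin * ly$filters,
                                   ly$k * cin, ly$k * ly$filters),
                    dim = c(ly$k, cin, ly$filters))
      ly$b <- numeric(ly$filters)
      shape <- c(shape[1], geo$t_out, ly$filters)
    } else if (ly$type == "maxpool1x2") {
      stopifnot(length(shape) == 3)
      shape <- c(shape[1], shape[2] %/% 2L, shape[3])
    } else if (ly$type == "flatten") {
      shape <- prod(shape)
    } else if (ly$type == "dense") {
      stopifnot(length(shape) == 1)
      ly$W <- matrix(glorot_uniform(shape * ly$units, shape, ly$units),
                     shape, ly$units)
      ly$b <- numeric(ly$units)
      shape <- ly$units
    } else if (ly$type == "dropout") {
      # shape unchanged
    } else stop("unknown layer type: ", ly$type)
    ly$out_shape <- shape
    layers[[i]] <- ly
  }
  structure(list(layers = layers, input_shape = input_shape,
                 trained = FALSE, loss_history = NULL),
            class = "nn_model")
}

relu <- function(x) { x[x < 0] <- 0; x }

# Forward pass. Returns list(out, pre_out, caches, maps) where `maps` collects
# post-activation outputs for layers named in `keep` (by index).
nn_forward <- function(model, X, training = FALSE, keep = integer(0)) {
  caches <- vector("list", length(model$layers))
  maps <- list()
  pre_out <- NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv1x") {
      xd <- dim(X)
      pre <- conv1x_forward(X, xd, ly$W, dim(ly$W), ly$b,
                            ly$stride, ly$pad_left, ly$t_out)
      out <- if (identical(ly$activation, "relu")) relu(pre) else pre
      caches[[i]] <- list(x = X, pre = pre)
      X <- out
    } else if (ly$type == "maxpool1x2") {
      mp <- maxpool1x2_forward(X, dim(X))
      caches[[i]] <- list(argmax = mp$argmax, in_dim = dim(X))
      X <- mp$y
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(X))
      X <- matrix(X, nrow = dim(X)[1])
    } else if (ly$type == "dense") {
      pre <- sweep(X %*% ly$W, 2, ly$b, "+")
      caches[[i]] <- list(x = X, pre = pre)
      if (identical(ly$activation, "relu")) {
        X <- relu(pre)
      } else if (identical(ly$activation, "sigmoid")) {
        pre_out <- pre
        X <- 1 / (1 + exp(-pre))
      } else if (identical(ly$activation, "softmax")) {
        pre_out <- pre
        e <- exp(pre - apply(pre, 1, max))
        X <- e / rowSums(e)
      } else {
        pre_out <- pre
        X <- pre
      }
    } else if (ly$type == "dropout") {
      if (training) {
        mask <- (runif(length(X)) >= ly$rate) / (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else caches[[i]] <- list(mask = NULL)
    }
    if (i %in% keep) maps[[as.character(i)]] <- X
  }
  list(out = X, pre_out = pre_out, caches = caches, maps = maps)
}

# Backward pass from the gradient w.r.t. the final PRE-activation (the loss
# functions fold the output nonlinearity into dZ). Returns per-layer grads.
nn_backward <- function(model, caches, dZ) {
  grads <- vector("list", length(model$layers))
  d <- dZ
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "dense") {
      cache <- caches[[i]]
      if (identical(ly$activation, "relu")) d <- d * (cache$pre > 0)
      grads[[i]] <- list(W = crossprod(cache$x, d), b = colSums(d))
      d <- tcrossprod(d, ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) d <- d * caches[[i]]$mask
    } else if (ly$type == "flatten") {
      d <- array(d, dim = caches[[i]]$in_dim)
    } else if (ly$type == "maxpool1x2") {
      d <- maxpool1x2_backward(d, caches[[i]]$argmax, caches[[i]]$in_dim)
    } else if (ly$type == "conv1x") {
      cache <- caches[[i]]
      if (identical(ly$activation, "relu")) d <- d * (cache$pre > 0)
      bw <- conv1x_backward(cache$x, dim(cache$x), ly$W, dim(ly$W), d,
                            ly$stride, ly$pad_left, ly$t_out)
      grads[[i]] <- list(W = bw$dw, b = bw$db)
      d <- bw$dx
    }
  }
  grads
}

nn_adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (!is.null(ly$W))
      list(mW = 0 * ly$W, vW = 0 * ly$W, mb = 0 * ly$b, vb = 0 * ly$b)
    else NULL
  })
}

nn_adam_step <- function(model, grads, state, t, lr, beta1, beta2, eps) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    corr1 <- 1 - beta1^t
    corr2 <- 1 - beta2^t
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

slice_batch <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE]
  else X[idx, , , , drop = FALSE]
}

nn_loss_grad <- function(out, pre, y, kind) {
  B <- nrow(pre)
  if (kind == "binary") {
    p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dZ <- (out - matrix(y, ncol = 1)) / B
  } else {
    K <- ncol(pre)
    Y <- matrix(0, B, K)
    Y[cbind(seq_len(B), y + 1L)] <- 1
    p <- pmin(pmax(out, 1e-12), 1)
    loss <- -mean(log(p[cbind(seq_len(B), y + 1L)]))
    dZ <- (out - Y) / B
  }
  list(loss = loss, dZ = dZ)
}

# Mini-batch Adam training loop. y: integer labels 0/1 (binary) or 0..K-1
# (categorical). Records the mean training loss of every pass in
# model$loss_history.
nn_fit <- function(model, X, y, epochs, batch_size, lr = 1e-2,
                   beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                   loss = c("binary", "categorical"), seed = NULL,
                   shuffle = TRUE) {
  loss <- match.arg(loss)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  state <- nn_adam_init(model)
  t <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- if (shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      bidx <- idx[start:min(start + batch_size - 1L, n)]
      Xb <- slice_batch(X, bidx)
      yb <- y[bidx]
      fw <- nn_forward(model, Xb, training = TRUE)
      lg <- nn_loss_grad(fw$out, fw$pre_out, yb, loss)
      grads <- nn_backward(model, fw$caches, lg$dZ)
      t <- t + 1L
      upd <- nn_adam_step(model, grads, state, t, lr, beta1, beta2, eps)
      model <- upd$model
      state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(bidx)
    }
    history[ep] <- ep_loss / n
  }
  model$trained <- TRUE
  model$loss_history <- history
  model
}

# Chunked inference; returns the network output (probabilities).
nn_predict <- function(model, X, chunk = 256L, keep = integer(0)) {
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  outs <- list()
  maps <- list()
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- nn_forward(model, slice_batch(X, idx), training = FALSE, keep = keep)
    outs[[length(outs) + 1L]] <- fw$out
    if (length(keep)) maps[[length(maps) + 1L]] <- fw$maps
  }
  out <- do.call(rbind, outs)
  if (length(keep)) list(out = out, map_chunks = maps) else out
}
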