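# Training and inference of the epoch CNN through the fused C++ stack
# (src/cnn_stack.cpp). The convolutional front (Conv1 -> Pool1 -> Conv2 ->
# Pool2 -> Dense1 pre-activation) runs in persistent C++ buffers; the small
# dense head (ReLU, dropout, Dense2, Dense3/sigmoid) and Adam live in R.

cnn_layer_index <- function(model, name) {
  for (i in seq_along(model$layers))
    if (identical(model$layers[[i]]$name, name)) return(i)
  stop("layer not found: ", name)
}

cnn_get_params <- function(model) {
  ix <- vapply(c("Conv1", "Conv2", "Dense1", "Dense2", "Dense3"),
               function(nm) cnn_layer_index(model, nm), integer(1))
  list(W1 = model$layers[[ix[1]]]$W, b1 = model$layers[[ix[1]]]$b,
       W2 = model$layers[[ix[2]]]$W, b2 = model$layers[[ix[2]]]$b,
       Wd1 = model$layers[[ix[3]]]$W, bd1 = model$layers[[ix[3]]]$b,
       Wd2 = model$layers[[ix[4]]]$W, bd2 = model$layers[[ix[4]]]$b,
       Wd3 = model$layers[[ix[5]]]$W, bd3 = model$layers[[ix[5]]]$b,
       dropout = model$layers[[cnn_layer_index(model, "Dropout")]]$rate)
}

cnn_set_params <- function(model, pa) {
  ix <- vapply(c("Conv1", "Conv2", "Dense1", "Dense2", "Dense3"),
               function(nm) cnn_layer_index(model, nm), integer(1))
  model$layers[[ix[1]]]$W <- pa$W1; model$layers[[ix[1]]]$b <- pa$b1
  model$layers[[ix[2]]]$W <- pa$W2; model$layers[[ix[2]]]$b <- pa$b2
  model$layers[[ix[3]]]$W <- pa$Wd1; model$layers[[ix[3]]]$b <- pa$bd1
  model$layers[[ix[4]]]$W <- pa$Wd2; model$layers[[ix[4]]]$b <- pa$bd2
  model$layers[[ix[5]]]$W <- pa$Wd3; model$layers[[ix[5]]]$b <- pa$bd3
  model
}

# Dense head forward/backward on the B x 32 Dense1 pre-activation.
cnn_head_forward <- function(D1, pa, training) {
  A1 <- relu(D1)
  mask <- NULL
  if (training && pa$dropout > 0) {
    mask <- (runif(length(A1)) >= pa$dropout) / (1 - pa$dropout)
    A1 <- A1 * mask
  }
  Z2 <- sweep(A1 %*% pa$Wd2, 2, pa$bd2, "+")
  A2 <- relu(Z2)
  Z3 <- sweep(A2 %*% pa$Wd3, 2, pa$bd3, "+")
  p <- 1 / (1 + exp(-Z3))
  list(p = p, A1 = A1, mask = mask, Z2 = Z2, A2 = A2, D1 = D1)
}

cnn_head_backward <- function(fw, pa, dZ3) {
  g <- list()
  g$Wd3 <- crossprod(fw$A2, dZ3); g$bd3 <- colSums(dZ3)
  dA2 <- tcrossprod(dZ3, pa$Wd3)
  dZ2 <- dA2 * (fw$Z2 > 0)
  g$Wd2 <- crossprod(fw$A1, dZ2); g$bd2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, pa$Wd2)
  if (!is.null(fw$mask)) dA1 <- dA1 * fw$mask
  dD1 <- dA1 * (fw$D1 > 0)
  list(grads = g, dD1 = dD1)
}

# Train on the rows `idx` of the full cohort tensor `X` (no copying of the
# training block: the C++ stack gathers batch rows directly).
cnn_train_idx <- function(model, X, idx, y, cfg) {
  stopifnot(length(idx) == length(y))
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  set.seed(cfg$seed)
  fresh <- nn_init(model$layers, model$spec$input_shape, seed = NULL)
  pa <- cnn_get_params(fresh)
  # unshare every parameter: the Adam update below mutates them in place
  pa <- lapply(pa, function(z) z + 0)
  pnames <- c("W1", "b1", "W2", "b2", "Wd1", "bd1", "Wd2", "bd2",
              "Wd3", "bd3")
  mstate <- lapply(pa[pnames], function(z) z * 0)
  vstate <- lapply(pa[pnames], function(z) z * 0)
  # preallocated gradient buffers for the conv stack (filled in place)
  g <- list(W1 = pa$W1 * 0, b1 = pa$b1 * 0, W2 = pa$W2 * 0, b2 = pa$b2 * 0,
            Wd1 = pa$Wd1 * 0, bd1 = pa$bd1 * 0)
  n <- length(idx)
  t <- 0L
  history <- numeric(cfg$epochs)
  cnn_stack_load(X, dim(X), model$spec$input_gain)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = cfg$batch_size)) {
      sl <- ord[s:min(s + cfg$batch_size - 1L, n)]
      bidx <- idx[sl]
      yb <- y[sl]
      B <- length(bidx)
      D1 <- cnn_stack_forward(as.integer(bidx),
                              pa$W1, dim(pa$W1), pa$b1,
                              pa$W2, dim(pa$W2), pa$b2,
                              pa$Wd1, pa$bd1, 2L, 2L)
      fw <- cnn_head_forward(D1, pa, training = TRUE)
      p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss -
        sum(yb * log(p) + (1 - yb) * log(1 - p))
      dZ3 <- (fw$p - matrix(yb, ncol = 1)) / B
      hb <- cnn_head_backward(fw, pa, dZ3)
      cnn_stack_backward_into(hb$dD1, pa$W1, dim(pa$W1),
                              pa$W2, dim(pa$W2), pa$Wd1,
                              g$W1, g$b1, g$W2, g$b2, g$Wd1, g$bd1)
      t <- t + 1L
      for (nm in pnames) {
        gnm <- if (!is.null(g[[nm]])) g[[nm]] else hb$grads[[nm]]
        adam_step_inplace(pa[[nm]], gnm, mstate[[nm]], vstate[[nm]], t,
                          cfg$learning_rate, cfg$beta1, cfg$beta2,
                          cfg$epsilon)
      }
    }
    history[ep] <- ep_loss / n
  }
  model <- cnn_set_params(model, pa)
  model$trained <- TRUE
  model$loss_history <- history
  model
}

cnn_predict_idx <- function(model, X, idx, chunk = 128L) {
  pa <- cnn_get_params(model)
  out <- numeric(length(idx))
  cnn_stack_load(X, dim(X), model$spec$input_gain)
  for (s in seq(1L, length(idx), by = chunk)) {
    sl <- s:min(s + chunk - 1L, length(idx))
    D1 <- cnn_stack_forward(as.integer(idx[sl]),
                            pa$W1, dim(pa$W1), pa$b1,
                            pa$W2, dim(pa$W2), pa$b2,
                            pa$Wd1, pa$bd1, 2L, 2L)
    out[sl] <- as.numeric(cnn_head_forward(D1, pa, training = FALSE)$p)
  }
  out
}
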