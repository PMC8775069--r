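test_that("the architecture table reproduces the reference design exactly", {
  m <- build_cnn()
  tab <- m$table
  expect_equal(tab$parameters[tab$layer == "Conv1"], 592L)
  expect_equal(tab$parameters[tab$layer == "Conv2"], 1568L)
  expect_equal(tab$parameters[tab$layer == "Dense1"], 622624L)
  expect_equal(tab$parameters[tab$layer == "Dense2"], 528L)
  expect_equal(tab$parameters[tab$layer == "Dense3"], 17L)
  expect_equal(sum(tab$parameters), 625329L)
  expect_equal(tab$output_shape,
               c("19 x 512 x 6", "19 x 256 x 16", "19 x 128 x 16",
                 "19 x 64 x 32", "19 x 32 x 32", "19456", "32", "32",
                 "16", "1"))
  # a dense toy layer: 1 input -> 1 output has weight + bias
  toy <- pnesnet:::nn_init(list(list(type = "dense", units = 1L,
                                     activation = "linear")), 1L, seed = 1)
  expect_equal(length(toy$layers[[1]]$W) + length(toy$layers[[1]]$b), 2L)
})

test_that("a wrong input shape fails construction with the layer named", {
  expect_error(build_cnn(cnn_spec(input_shape = c(19L, 256L, 6L))),
               "Conv1|Dense1")
})

test_that("the convolution layer matches a hand-rolled oracle", {
  # 1 x 8 x 1 toy input, one 1 x 3 filter, stride 2, same padding
  X <- array(1:8, dim = c(1, 1, 8, 1))
  W <- array(c(0.5, -1, 2), dim = c(3, 1, 1))
  geo <- pnesnet:::conv_same_geometry(8, 3, 2)
  Y <- pnesnet:::conv1x_forward(X, dim(X), W, dim(W), 0.25, 2L,
                                geo$pad_left, geo$t_out)
  oracle <- vapply(c(1, 3, 5, 7), function(s) {
    win <- c(1:8, 0)[s:(s + 2)]
    sum(win * c(0.5, -1, 2)) + 0.25
  }, numeric(1))
  expect_equal(as.numeric(Y), oracle)
})

test_that("fused float stack agrees with the double-precision engine", {
  set.seed(42)
  Xs <- array(rnorm(4 * 19 * 512 * 6) * 10, dim = c(4, 19, 512, 6))
  m <- build_cnn(seed = 5)
  gain <- m$spec$input_gain
  fw <- pnesnet:::nn_forward(m, Xs * gain, training = FALSE)
  pa <- pnesnet:::cnn_get_params(m)
  pnesnet:::cnn_stack_load(Xs, dim(Xs), gain)
  D1 <- pnesnet:::cnn_stack_forward(1:4, pa$W1, dim(pa$W1), pa$b1,
                                    pa$W2, dim(pa$W2), pa$b2,
                                    pa$Wd1, pa$bd1, 2L, 2L)
  p_stack <- pnesnet:::cnn_head_forward(D1, pa, FALSE)$p
  expect_equal(as.numeric(p_stack), as.numeric(fw$out), tolerance = 1e-5)

  # gradients of both routes agree at float precision
  y <- c(0, 1, 0, 1)
  lg <- pnesnet:::nn_loss_grad(fw$out, fw$pre_out, y, "binary")
  gr <- pnesnet:::nn_backward(m, fw$caches, lg$dZ)
  fh <- pnesnet:::cnn_head_forward(D1, pa, FALSE)
  hb <- pnesnet:::cnn_head_backward(fh, pa, (fh$p - matrix(y, ncol = 1)) / 4)
  sb <- pnesnet:::cnn_stack_backward(hb$dD1, pa$W1, dim(pa$W1),
                                     pa$W2, dim(pa$W2), pa$Wd1)
  expect_equal(sb$dW1, gr[[1]]$W, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(sb$dW2, gr[[3]]$W, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(as.numeric(sb$dWd1), as.numeric(gr[[6]]$W), tolerance = 1e-4)
})

test_that("training reduces cross-entropy, is seeded, and rejects bad input", {
  tens <- tiny_cohort_tensors(seed = 2, delta = 2, subjects = 2L,
                              epochs = 12L)
  xy <- cohort_xy(tens)
  cfg <- train_config(epochs = 4, batch_size = 16L, seed = 7)
  m1 <- train_cnn(build_cnn(), xy$X, xy$y, cfg)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])
  m2 <- train_cnn(build_cnn(), xy$X, xy$y, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(pnesnet:::cnn_get_params(m1)$Wd3,
                   pnesnet:::cnn_get_params(m2)$Wd3)

  expect_error(train_cnn(build_cnn(), xy$X, rep(1L, length(xy$y)), cfg),
               "both classes")
  expect_error(train_cnn(build_cnn(), xy$X, xy$y[-1], cfg), "labels length")
})

test_that("training cross-entropy is non-increasing in nearly every pass", {
  tens <- tiny_cohort_tensors(seed = 9, delta = 2, subjects = 2L,
                              epochs = 10L)
  xy <- cohort_xy(tens)
  m <- train_cnn(build_cnn(), xy$X, xy$y,
                 train_config(epochs = 10, batch_size = 20L, seed = 3))
  increases <- sum(diff(m$loss_history) > 1e-8)
  expect_lte(increases, 2L)  # non-increasing in >= 8 of 10 passes
})

test_that("prediction outputs are probabilities with the documented behaviour", {
  tens <- tiny_cohort_tensors(seed = 6, delta = 2, subjects = 2L,
                              epochs = 8L)
  xy <- cohort_xy(tens)
  m <- train_cnn(build_cnn(), xy$X, xy$y,
                 train_config(epochs = 3, batch_size = 16L, seed = 1))
  p <- predict_epochs(m, xy$X)
  expect_length(p, length(xy$y))
  expect_true(all(p >= 0 & p <= 1))
  # identical all-zero epochs give one shared constant output
  Z <- array(0, dim = c(3, 19, 512, 6))
  pz <- predict_epochs(m, Z)
  expect_equal(pz, rep(pz[1], 3), tolerance = 1e-6)
  # untrained model refuses to predict
  expect_error(predict_epochs(build_cnn(), xy$X), "not been trained")
})

test_that("predictions track tensor content, not stale activation caches", {
  tens <- tiny_cohort_tensors(seed = 3, delta = 2, subjects = 1L,
                              epochs = 6L)
  xy <- cohort_xy(tiny_cohort_tensors(seed = 5, delta = 2, subjects = 2L,
                                      epochs = 6L))
  m <- train_cnn(build_cnn(), xy$X, xy$y,
                 train_config(epochs = 2, batch_size = 12L, seed = 2))
  X <- tens[[1]]$tensor$values
  p1 <- predict_epochs(m, X)
  Xmod <- X
  Xmod[3, 5, 101:200, 3] <- Xmod[3, 5, 101:200, 3] + 50
  p2 <- predict_epochs(m, Xmod)
  expect_false(isTRUE(all.equal(p1, p2)))
  expect_equal(predict_epochs(m, X), p1)
})

test_that("feature maps have the documented shapes and are rectified", {
  tens <- tiny_cohort_tensors(seed = 6, delta = 2, subjects = 2L,
                              epochs = 4L)
  xy <- cohort_xy(tens)
  m <- train_cnn(build_cnn(), xy$X, xy$y,
                 train_config(epochs = 2, batch_size = 8L, seed = 1))
  inp <- extract_feature_maps(m, xy$X, "input")
  expect_equal(dim(inp), dim(xy$X))
  c1 <- extract_feature_maps(m, xy$X, "Conv1")
  expect_equal(dim(c1), c(dim(xy$X)[1], 19L, 256L, 16L))
  c2 <- extract_feature_maps(m, xy$X, "Conv2")
  expect_equal(dim(c2), c(dim(xy$X)[1], 19L, 64L, 32L))
  expect_true(all(c1 >= 0))
  expect_true(all(c2 >= 0))
  expect_error(extract_feature_maps(m, xy$X, "Dense1"), "arg")
})
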