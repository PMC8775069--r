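#' CNN architecture specification
#'
#' The fixed epoch-classification architecture: two 1 x k convolutions with
#' ReLU (16 filters of 1 x 6, then 32 of 1 x 3; stride 1 x 2, "same" padding),
#' each followed by 1 x 2 max pooling, then Flatten, Dense(32), Dropout(0.3),
#' Dense(16) and a single sigmoid output unit. Channels (19) form the spatial
#' height, time (512) the width, and the six wavelet sub-bands the input
#' feature channels; all convolution and pooling acts along time only.
#'
#' @param input_shape Integer triple (channels, samples, bands);
#'   default `c(19, 512, 6)`.
#' @param conv1_filters,conv1_k,conv2_filters,conv2_k,dense1,dense2,dropout
#'   Architecture knobs, defaulting to the reference design.
#' @param input_gain Fixed scalar applied to the input tensor inside the
#'   network (default 0.02, i.e. amplitudes are expressed in units of 50
#'   microvolts). This is a dimensional rescaling for numerical conditioning
#'   -- with microvolt-scale sub-band signals and a 19456-wide flatten, unit
#'   gain saturates the sigmoid head at initialisation. It is not
#'   data-dependent normalisation (none is applied; see the methods
#'   vignette).
#' @return Object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = c(19L, 512L, 6L),
                     conv1_filters = 16L, conv1_k = 6L,
                     conv2_filters = 32L, conv2_k = 3L,
                     dense1 = 32L, dense2 = 16L, dropout = 0.3,
                     input_gain = 0.02) {
  structure(list(input_shape = as.integer(input_shape),
                 conv1_filters = conv1_filters, conv1_k = conv1_k,
                 conv2_filters = conv2_filters, conv2_k = conv2_k,
                 dense1 = dense1, dense2 = dense2, dropout = dropout,
                 input_gain = input_gain),
            class = "cnn_spec")
}

cnn_layer_stack <- function(spec) {
  list(
    list(type = "conv1x", filters = spec$conv1_filters, k = spec$conv1_k,
         stride = 2L, activation = "relu", name = "Conv1"),
    list(type = "maxpool1x2", name = "MaxPool1"),
    list(type = "conv1x", filters = spec$conv2_filters, k = spec$conv2_k,
         stride = 2L, activation = "relu", name = "Conv2"),
    list(type = "maxpool1x2", name = "MaxPool2"),
    list(type = "flatten", name = "Flatten"),
    list(type = "dense", units = spec$dense1, activation = "relu",
         name = "Dense1"),
    list(type = "dropout", rate = spec$dropout, name = "Dropout"),
    list(type = "dense", units = spec$dense2, activation = "relu",
         name = "Dense2"),
    list(type = "dense", units = 1L, activation = "sigmoid", name = "Dense3"))
}

shape_string <- function(shape) paste(shape, collapse = " x ")

#' Build the CNN and derive its shape / parameter table
#'
#' Instantiates the network (Glorot-uniform weights, zero biases) and computes
#' the per-layer output shapes and learnable-parameter counts without any
#' training. With the default [cnn_spec()] the table must reproduce the
#' reference architecture exactly (Conv1 592, Conv2 1568, Dense1 622624,
#' Dense2 528, Dense3 17; total 625329; flatten size 19456); a mismatch stops
#' with the offending layer named.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for the weight initialisation (default 1).
#' @param validate If `TRUE` (default), a spec with the reference filter and
#'   dense sizes must reproduce the reference shape/parameter table exactly;
#'   set to `FALSE` to build deliberately non-standard geometries.
#' @return Object of class `cnn_model`: the layer stack plus `$table`, a data
#'   frame with columns `layer`, `output_shape`, `parameters`.
#' @export
#' @examples
#' m <- build_cnn()
#' m$table
#' sum(m$table$parameters)  # 625329
build_cnn <- function(spec = cnn_spec(), seed = 1, validate = TRUE) {
  stopifnot(inherits(spec, "cnn_spec"))
  model <- nn_init(cnn_layer_stack(spec), spec$input_shape, seed = seed)
  rows <- data.frame(layer = "Input",
                     output_shape = shape_string(spec$input_shape),
                     parameters = 0L, stringsAsFactors = FALSE)
  for (ly in model$layers) {
    np <- if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L
    rows <- rbind(rows, data.frame(layer = ly$name,
                                   output_shape = shape_string(ly$out_shape),
                                   parameters = np))
  }
  model$table <- rows
  model$spec <- spec
  if (validate &&
      spec$conv1_filters == 16L && spec$conv1_k == 6L &&
      spec$conv2_filters == 32L && spec$conv2_k == 3L &&
      spec$dense1 == 32L && spec$dense2 == 16L) {
    expected <- list(Conv1 = list("19 x 256 x 16", 592L),
                     MaxPool1 = list("19 x 128 x 16", 0L),
                     Conv2 = list("19 x 64 x 32", 1568L),
                     MaxPool2 = list("19 x 32 x 32", 0L),
                     Flatten = list("19456", 0L),
                     Dense1 = list("32", 622624L),
                     Dense2 = list("16", 528L),
                     Dense3 = list("1", 17L))
    for (nm in names(expected)) {
      r <- rows[rows$layer == nm, ]
      if (r$output_shape != expected[[nm]][[1]] ||
          r$parameters != expected[[nm]][[2]])
        stop("layer ", nm, " deviates from the reference architecture: got ",
             r$output_shape, " / ", r$parameters, " parameters")
    }
  }
  class(model) <- c("cnn_model", class(model))
  model
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model>", if (x$trained) "trained" else "untrained", "\n")
  print(x$table, row.names = FALSE)
  cat("Total parameters:", sum(x$table$parameters), "\n")
  invisible(x)
}

#' Training configuration for the CNN
#'
#' Adam with the reference settings: learning rate `1e-2`, first/second moment
#' decay 0.9 / 0.999, binary cross-entropy, batch size 107, 10 passes over the
#' training set.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param batch_size Mini-batch size (default 107).
#' @param epochs Number of passes over the training data (default 10).
#' @param seed Integer seed controlling shuffling, dropout and (via
#'   [train_cnn()]) weight re-initialisation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-2, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 107L, epochs = 10L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

tensor_values <- function(tensor) {
  if (inherits(tensor, "subband_tensor")) tensor$values
  else if (is.array(tensor) && length(dim(tensor)) == 4) tensor
  else stop("expected a subband_tensor or a 4-D array")
}

#' Train the CNN on epoch labels
#'
#' Epoch labels follow the sigmoid convention: PNES = 0, ES = 1. Training is
#' fully seeded (weights, shuffling, dropout) and records the per-pass mean
#' training cross-entropy in `$loss_history`.
#'
#' @param model A [build_cnn()] model (untrained or trained; weights are
#'   re-initialised from `cfg$seed`).
#' @param tensor A [build_epoch_tensor()] result (or 4-D array) with one slice
#'   per epoch.
#' @param labels Integer/numeric vector of per-epoch labels in `{0, 1}`; both
#'   classes must be present.
#' @param cfg A [train_config()].
#' @return The fitted `cnn_model`.
#' @export
train_cnn <- function(model, tensor, labels, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  X <- tensor_values(tensor)
  if (dim(X)[1] != length(labels))
    stop("labels length must equal the number of epochs")
  labels <- as.integer(labels)
  cnn_train_idx(model, X, seq_len(dim(X)[1]), labels, cfg)
}

#' Per-epoch class probabilities
#'
#' @param model A trained `cnn_model`.
#' @param tensor Sub-band tensor of epochs to score.
#' @return Numeric vector of sigmoid outputs in `[0, 1]` (probability of the
#'   ES class); thresholding at 0.5 gives epoch labels.
#' @export
predict_epochs <- function(model, tensor) {
  stopifnot(inherits(model, "cnn_model"))
  if (!model$trained) stop("model has not been trained")
  X <- tensor_values(tensor)
  cnn_predict_idx(model, X, seq_len(dim(X)[1]))
}

#' Extract input or intermediate feature maps
#'
#' Returns the post-ReLU activation arrays of the convolutional layers (or the
#' input tensor itself) for every epoch: shapes per epoch are
#' `(19, 512, 6)` for `input`, `(19, 256, 16)` for `Conv1` and `(19, 64, 32)`
#' for `Conv2` under the default architecture.
#'
#' @param model A trained `cnn_model`.
#' @param tensor Sub-band tensor of epochs.
#' @param layer One of `"input"`, `"Conv1"`, `"Conv2"`.
#' @return 4-D array, epochs x channels x time x filters.
#' @export
extract_feature_maps <- function(model, tensor,
                                 layer = c("input", "Conv1", "Conv2")) {
  stopifnot(inherits(model, "cnn_model"))
  layer <- match.arg(layer)
  X <- tensor_values(tensor)
  if (layer == "input") return(X)
  if (!model$trained) stop("model has not been trained")
  pa <- cnn_get_params(model)
  n <- dim(X)[1]
  chunk <- 128L
  out <- NULL
  cnn_stack_load(X, dim(X), model$spec$input_gain)
  for (s in seq(1L, n, by = chunk)) {
    sl <- s:min(s + chunk - 1L, n)
    cnn_stack_forward(as.integer(sl),
                      pa$W1, dim(pa$W1), pa$b1,
                      pa$W2, dim(pa$W2), pa$b2,
                      pa$Wd1, pa$bd1, 2L, 2L)
    act <- cnn_stack_activation(layer)
    if (is.null(out)) {
      d1 <- dim(act)
      out <- array(0, dim = c(n, d1[2], d1[3], d1[4]))
    }
    out[sl, , , ] <- act
  }
  out
}
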