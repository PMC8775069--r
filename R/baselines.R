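#' Baseline classifier configuration
#'
#' The six comparison classifiers trained on handcrafted sub-band features:
#' three multi-layer perceptrons (MLP1: 300; MLP2: 300-50; MLP3: 300-100-50;
#' ReLU hidden units, softmax output, Adam, batch 214, 10 passes), an RBF
#' SVM with kernel width `gamma = 0.001`, LDA (plain moment estimates, no
#' shrinkage) and QDA (no regularisation).
#'
#' @param name One of `"MLP1"`, `"MLP2"`, `"MLP3"`, `"SVMrbf"`, `"LDA"`,
#'   `"QDA"`.
#' @param seed Integer seed for stochastic fits.
#' @param scale If `TRUE`, z-score features (train statistics) before
#'   SVM/LDA/QDA/MLP; off by default, provided for sensitivity analysis.
#' @param ... Overrides: `hidden` (MLP layer sizes), `gamma`, `C` (SVM),
#'   `batch_size`, `epochs`, `learning_rate` (MLPs).
#' @return Object of class `baseline_config`.
#' @export
baseline_config <- function(name = c("MLP1", "MLP2", "MLP3", "SVMrbf",
                                     "LDA", "QDA"),
                            seed = 1L, scale = FALSE, ...) {
  name <- match.arg(name)
  defaults <- list(
    MLP1 = list(hidden = 300L),
    MLP2 = list(hidden = c(300L, 50L)),
    MLP3 = list(hidden = c(300L, 100L, 50L)),
    SVMrbf = list(gamma = 0.001, C = 1),
    LDA = list(), QDA = list())[[name]]
  cfg <- utils::modifyList(
    c(defaults, list(batch_size = 214L, epochs = 10L, learning_rate = 1e-2)),
    list(...))
  structure(c(list(name = name, seed = as.integer(seed), scale = scale), cfg),
            class = "baseline_config")
}

# MASS discriminant fits reject variables whose within-group sd falls below
# an absolute tolerance, which tiny-amplitude sub-band features can trip.
# LDA/QDA posteriors are invariant under per-variable rescaling, so columns
# are standardised internally and (near-)constant-within-group columns --
# which carry no discriminative information -- are dropped; the transform is
# kept for prediction.
discriminant_fit <- function(fun, X, y) {
  g <- factor(y, levels = c(0, 1))
  sdall <- apply(X, 2, stats::sd)
  sdall[sdall == 0] <- 1
  Xs <- sweep(X, 2, sdall, "/")
  wsd <- pmin(apply(Xs[g == "0", , drop = FALSE], 2, stats::sd),
              apply(Xs[g == "1", , drop = FALSE], 2, stats::sd))
  drop_const <- which(wsd <= 1e-3)
  Xu <- if (length(drop_const)) Xs[, -drop_const, drop = FALSE] else Xs
  list(fit = fun(Xu, grouping = g), drop = drop_const, col_scale = sdall)
}

mlp_layers <- function(hidden) {
  c(lapply(hidden, function(h)
      list(type = "dense", units = as.integer(h), activation = "relu")),
    list(list(type = "dense", units = 2L, activation = "softmax")))
}

#' Train a baseline classifier on a feature matrix
#'
#' @param cfg A [baseline_config()].
#' @param X epochs x features numeric matrix (see [tensor_features()]).
#' @param y Per-epoch labels in `{0, 1}` (ES = 1); both classes required.
#' @return Object of class `baseline_fit` exposing per-epoch ES probabilities
#'   through [predict_baseline()].
#' @export
train_baseline <- function(cfg, X, y) {
  stopifnot(inherits(cfg, "baseline_config"))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  scaling <- NULL
  if (isTRUE(cfg$scale)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    scaling <- list(mu = mu, sd = sdv)
  }
  fit <- switch(
    cfg$name,
    MLP1 = , MLP2 = , MLP3 = {
      set.seed(cfg$seed)
      m <- nn_init(mlp_layers(cfg$hidden), ncol(X), seed = NULL)
      nn_fit(m, X, y, epochs = cfg$epochs, batch_size = cfg$batch_size,
             lr = cfg$learning_rate, loss = "categorical", seed = NULL)
    },
    SVMrbf = svm_rbf_fit(X, y, gamma = cfg$gamma, C = cfg$C,
                         seed = cfg$seed),
    LDA = discriminant_fit(MASS::lda, X, y),
    QDA = discriminant_fit(MASS::qda, X, y))
  structure(list(name = cfg$name, fit = fit, scaling = scaling),
            class = "baseline_fit")
}

#' Per-epoch ES probabilities from a baseline fit
#'
#' @param object A [train_baseline()] result.
#' @param X epochs x features matrix.
#' @return Numeric vector in `[0, 1]` (SVM decision values are mapped through
#'   a logistic link so that 0.5 corresponds to the decision boundary).
#' @export
predict_baseline <- function(object, X) {
  stopifnot(inherits(object, "baseline_fit"))
  if (!is.null(object$scaling))
    X <- sweep(sweep(X, 2, object$scaling$mu), 2, object$scaling$sd, "/")
  switch(
    object$name,
    MLP1 = , MLP2 = , MLP3 = nn_predict(object$fit, X)[, 2],
    SVMrbf = 1 / (1 + exp(-svm_rbf_decision(object$fit, X))),
    LDA = , QDA = {
      Xs <- sweep(X, 2, object$fit$col_scale, "/")
      drop_const <- object$fit$drop
      Xu <- if (length(drop_const)) Xs[, -drop_const, drop = FALSE] else Xs
      as.numeric(predict(object$fit$fit, Xu)$posterior[, "1"])
    })
}

#' LOOCV of a baseline classifier on cohort features
#'
#' @param tensors Output of [cohort_tensors()].
#' @param cfg A [baseline_config()].
#' @param verbose Print per-fold progress.
#' @return See [run_loocv()]; features are extracted once per subject with
#'   [tensor_features()].
#' @export
loocv_baseline <- function(tensors, cfg, verbose = FALSE) {
  feats <- lapply(tensors, function(su)
    list(subject_id = su$subject_id, class_label = su$class_label,
         features = tensor_features(su$tensor)))
  run_loocv(
    feats,
    fit_fun = function(X, y, fold) {
      fcfg <- cfg
      fcfg$seed <- cfg$seed + fold
      train_baseline(fcfg, X, y)
    },
    predict_fun = function(fit, X) predict_baseline(fit, X),
    verbose = verbose)
}
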