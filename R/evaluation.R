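#' Subject-wise leave-one-out folds
#'
#' Every subject serves exactly once as the held-out test case; the remaining
#' subjects form the training fold. Cohorts whose removal of one subject would
#' leave a single-class training fold are rejected.
#'
#' @param cohort List of subjects, each with a `class_label` field (as
#'   produced by [generate_cohort()] or [cohort_tensors()]).
#' @param require_both_classes If `TRUE` (the default of the LOOCV drivers),
#'   reject cohorts in which some training fold would contain a single class;
#'   the plain partition (default) accepts any cohort of two or more
#'   subjects.
#' @return List of folds: each a list with `train` (indices) and `test`
#'   (one index).
#' @export
loocv_folds <- function(cohort, require_both_classes = FALSE) {
  n <- length(cohort)
  if (n < 2) stop("need at least two subjects")
  cls <- vapply(cohort, function(s) s$class_label, character(1))
  lapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    if (require_both_classes && length(unique(cls[tr])) < 2)
      stop("training fold for subject ", i, " would contain a single class")
    list(train = tr, test = i)
  })
}

#' Patient-level majority label from epoch probabilities
#'
#' Epochs are labelled by thresholding the sigmoid output at 0.5
#' (ES above, PNES below); the subject is assigned to the class holding the
#' majority of epoch labels. An exact 50/50 tie is broken by the mean epoch
#' probability against 0.5.
#'
#' @param epoch_probabilities Non-empty numeric vector of per-epoch ES
#'   probabilities.
#' @return List with `class` (`"ES"` or `"PNES"`) and `fraction` (share of
#'   epochs voting for the assigned class).
#' @export
subject_label <- function(epoch_probabilities) {
  if (length(epoch_probabilities) == 0) stop("no epoch probabilities given")
  es <- epoch_probabilities > 0.5
  f_es <- mean(es)
  cls <- if (f_es > 0.5) "ES"
         else if (f_es < 0.5) "PNES"
         else if (mean(epoch_probabilities) > 0.5) "ES" else "PNES"
  list(class = cls, fraction = if (cls == "ES") f_es else 1 - f_es)
}

#' Confusion matrix over subjects (positive class: PNES)
#'
#' `TP`/`TN` count PNES and ES subjects classified correctly; `FP` counts ES
#' subjects called PNES, `FN` PNES subjects called ES. Note the positive class
#' for the metric suite is PNES even though the network's sigmoid encodes
#' ES = 1.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn),
                 positive_class = "PNES"),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metric suite
#'
#' Accuracy, precision, recall, F-measure and Cohen's kappa from a subject
#' confusion matrix, with kappa in its 2x2 closed form
#' `2(TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))`. Metrics whose
#' denominator vanishes are reported as 0 and flagged in `$degenerate`.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f_measure`, `cohens_kappa` (proportions in
#'   `[-1, 1]`) and `degenerate` (character vector of zero-denominator
#'   metrics).
#' @export
#' @examples
#' m <- compute_metrics(confusion_matrix(18, 16, 2, 0))
#' round(100 * c(m$accuracy, m$f_measure, m$cohens_kappa), 1)
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  acc <- (tp + tn) / total
  prec <- safe_ratio(tp, tp + fp)
  rec <- safe_ratio(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  kden <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  kap <- safe_ratio(2 * (tp * tn - fn * fp), kden)
  vals <- c(precision = prec, recall = rec, f_measure = f1,
            cohens_kappa = kap)
  degenerate <- names(vals)[is.na(vals)]
  if (length(degenerate))
    warning("zero-denominator metrics reported as 0: ",
            paste(degenerate, collapse = ", "))
  vals[is.na(vals)] <- 0
  structure(list(accuracy = acc, precision = vals[["precision"]],
                 recall = vals[["recall"]], f_measure = vals[["f_measure"]],
                 cohens_kappa = vals[["cohens_kappa"]],
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%%  precision %.1f%%  recall %.1f%%  F %.1f%%  kappa %.1f%%\n",
    100 * x$accuracy, 100 * x$precision, 100 * x$recall,
    100 * x$f_measure, 100 * x$cohens_kappa))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC, equivalent to the trapezoidal rule with tied
#' scores receiving half credit. Scores are oriented as probabilities of the
#' ES class; `true_labels` may be `"ES"`/`"PNES"` or 1/0.
#'
#' @param subject_scores Numeric scores (e.g. mean epoch probability per
#'   subject).
#' @param true_labels Class labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(subject_scores, true_labels) {
  y <- if (is.character(true_labels) || is.factor(true_labels))
    as.integer(as.character(true_labels) == "ES") else as.integer(true_labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(subject_scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stack per-subject epoch containers (4-D arrays or feature matrices).
bind_epochs <- function(xs) {
  if (is.matrix(xs[[1]])) return(do.call(rbind, xs))
  ds <- vapply(xs, function(x) dim(x)[1], numeric(1))
  d1 <- dim(xs[[1]])
  out <- array(0, dim = c(sum(ds), d1[2], d1[3], d1[4]))
  at <- 1L
  for (x in xs) {
    nb <- dim(x)[1]
    out[at:(at + nb - 1L), , , ] <- x
    at <- at + nb
  }
  out
}

subject_X <- function(su) {
  if (!is.null(su$tensor)) su$tensor$values
  else if (!is.null(su$features)) su$features
  else stop("subject carries neither a tensor nor a feature matrix")
}

#' Run subject-wise LOOCV with any epoch classifier
#'
#' Generic driver: for every fold the classifier is fitted on all other
#' subjects' epochs (labels: ES = 1, PNES = 0) and scores the held-out
#' subject's epochs; the subject is labelled by [subject_label()] and the
#' subject-level ROC score is the mean epoch probability.
#'
#' @param subjects List of subjects, each with `subject_id`, `class_label`,
#'   and either `tensor` (a [build_epoch_tensor()] result) or `features`
#'   (an epochs x p matrix).
#' @param fit_fun `function(X, y, fold)` returning a fitted classifier.
#' @param predict_fun `function(fit, X)` returning per-epoch ES probabilities.
#' @param verbose Print per-fold progress.
#' @return List with `per_subject` (data frame: subject, truth, predicted,
#'   fraction, score), `cm` ([confusion_matrix()]), `metrics`
#'   ([compute_metrics()] output) and `auc`.
#' @export
run_loocv <- function(subjects, fit_fun, predict_fun, verbose = FALSE) {
  folds <- loocv_folds(subjects, require_both_classes = TRUE)
  cls <- vapply(subjects, function(s) s$class_label, character(1))
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    Xtr <- bind_epochs(lapply(subjects[fold$train], subject_X))
    ytr <- unlist(lapply(subjects[fold$train], function(su) {
      nk <- if (!is.null(su$tensor)) dim(su$tensor$values)[1]
            else nrow(su$features)
      rep(as.integer(su$class_label == "ES"), nk)
    }))
    fit <- fit_fun(Xtr, ytr, f)
    probs <- predict_fun(fit, subject_X(subjects[[fold$test]]))
    lab <- subject_label(probs)
    rows[[f]] <- data.frame(subject = subjects[[fold$test]]$subject_id,
                            truth = cls[fold$test], predicted = lab$class,
                            fraction = lab$fraction, score = mean(probs),
                            stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fold %d/%d: %s -> %s", f, length(folds),
                      cls[fold$test], lab$class))
  }
  per_subject <- do.call(rbind, rows)
  cm <- confusion_matrix(
    tp = sum(per_subject$truth == "PNES" & per_subject$predicted == "PNES"),
    tn = sum(per_subject$truth == "ES" & per_subject$predicted == "ES"),
    fp = sum(per_subject$truth == "ES" & per_subject$predicted == "PNES"),
    fn = sum(per_subject$truth == "PNES" & per_subject$predicted == "ES"))
  list(per_subject = per_subject, cm = cm, metrics = compute_metrics(cm),
       auc = roc_auc(per_subject$score, per_subject$truth))
}

#' LOOCV of the sub-band CNN on a cohort
#'
#' Convenience wrapper around [run_loocv()] using [train_cnn()] /
#' [predict_epochs()]; each fold re-initialises and trains from
#' `cfg$seed + fold`.
#'
#' @param tensors Output of [cohort_tensors()].
#' @param cfg A [train_config()].
#' @param spec A [cnn_spec()].
#' @param verbose Print per-fold progress.
#' @return See [run_loocv()].
#' @export
loocv_cnn <- function(tensors, cfg = train_config(), spec = cnn_spec(),
                      verbose = FALSE) {
  base <- build_cnn(spec, seed = cfg$seed)
  X <- bind_epochs(lapply(tensors, subject_X))
  counts <- vapply(tensors, function(su) dim(su$tensor$values)[1], numeric(1))
  ends <- cumsum(counts)
  spans <- Map(function(s, e) s:e, c(1, utils::head(ends, -1) + 1), ends)
  y_all <- unlist(Map(function(su, n)
    rep(as.integer(su$class_label == "ES"), n), tensors, counts))
  folds <- loocv_folds(tensors, require_both_classes = TRUE)
  cls <- vapply(tensors, function(s) s$class_label, character(1))
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tr_idx <- unlist(spans[fold$train])
    fcfg <- cfg
    fcfg$seed <- cfg$seed + f
    fit <- cnn_train_idx(base, X, tr_idx, y_all[tr_idx], fcfg)
    probs <- cnn_predict_idx(fit, X, spans[[fold$test]])
    lab <- subject_label(probs)
    rows[[f]] <- data.frame(subject = tensors[[fold$test]]$subject_id,
                            truth = cls[fold$test], predicted = lab$class,
                            fraction = lab$fraction, score = mean(probs),
                            stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fold %d/%d: %s -> %s", f, length(folds),
                      cls[fold$test], lab$class))
  }
  per_subject <- do.call(rbind, rows)
  cm <- confusion_matrix(
    tp = sum(per_subject$truth == "PNES" & per_subject$predicted == "PNES"),
    tn = sum(per_subject$truth == "ES" & per_subject$predicted == "ES"),
    fp = sum(per_subject$truth == "ES" & per_subject$predicted == "PNES"),
    fn = sum(per_subject$truth == "PNES" & per_subject$predicted == "ES"))
  list(per_subject = per_subject, cm = cm, metrics = compute_metrics(cm),
       auc = roc_auc(per_subject$score, per_subject$truth))
}
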