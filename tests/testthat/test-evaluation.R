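fake_cohort <- function(n_es, n_pnes) {
  c(lapply(seq_len(n_es), function(i)
      list(subject_id = paste0("ES", i), class_label = "ES")),
    lapply(seq_len(n_pnes), function(i)
      list(subject_id = paste0("PNES", i), class_label = "PNES")))
}

test_that("LOOCV folds partition the cohort", {
  coh <- fake_cohort(18, 18)
  folds <- loocv_folds(coh)
  expect_length(folds, 36L)
  expect_setequal(vapply(folds, `[[`, 0L, "test"), seq_len(36))
  for (f in folds) {
    expect_length(f$train, 35L)
    expect_false(f$test %in% f$train)
  }
  expect_length(loocv_folds(fake_cohort(1, 1)), 2L)
  expect_error(loocv_folds(fake_cohort(1, 0)), "two subjects")
  expect_error(loocv_folds(fake_cohort(1, 2), require_both_classes = TRUE),
               "single class")
  # the LOOCV driver enforces two-class training folds
  bad <- lapply(fake_cohort(1, 2), function(s) {
    s$features <- matrix(0, 2, 2); s
  })
  expect_error(run_loocv(bad, function(X, y, f) NULL,
                         function(fit, X) rep(0.5, nrow(X))),
               "single class")
})

test_that("subject labelling follows the majority rule with the tie-break", {
  p <- c(rep(0.9, 120), rep(0.1, 94))  # 120 of 214 epochs called ES
  lab <- subject_label(p)
  expect_equal(lab$class, "ES")
  expect_equal(lab$fraction, 120 / 214)

  lab2 <- subject_label(rep(0.2, 50))
  expect_equal(lab2$class, "PNES")
  expect_equal(lab2$fraction, 1)

  # exact 107/214 tie resolved by mean probability (0.62 -> ES)
  p3 <- c(rep(0.99, 107), rep(0.25, 107))
  expect_equal(mean(p3), 0.62)
  expect_equal(subject_label(p3)$class, "ES")
  p4 <- c(rep(0.6, 107), rep(0.01, 107))
  expect_equal(subject_label(p4)$class, "PNES")

  expect_error(subject_label(numeric(0)), "no epoch")
})

test_that("metric suite matches the published worked examples", {
  m <- compute_metrics(confusion_matrix(18, 16, 2, 0))
  expect_equal(round(100 * m$accuracy, 1), 94.4)
  expect_equal(round(100 * m$recall, 1), 100)
  expect_equal(round(100 * m$f_measure, 1), 94.7)
  # printed value is 88.8 (truncated); the exact ratio is 576/648
  expect_equal(m$cohens_kappa, 576 / 648, tolerance = 1e-12)

  m2 <- compute_metrics(confusion_matrix(10, 4, 14, 8))
  expect_equal(round(100 * m2$cohens_kappa, 1), -22.2)
  expect_equal(round(100 * m2$accuracy, 1), 38.9)

  perfect <- compute_metrics(confusion_matrix(5, 5, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$cohens_kappa, 1)
})

test_that("metrics agree with a brute-force reference on all small matrices", {
  brute <- function(tp, tn, fp, fn) {
    total <- tp + tn + fp + fn
    pred <- c(rep("P", tp), rep("E", tn), rep("P", fp), rep("E", fn))
    truth <- c(rep("P", tp), rep("E", tn), rep("E", fp), rep("P", fn))
    acc <- mean(pred == truth)
    prec <- if (sum(pred == "P") == 0) 0 else
      sum(pred == "P" & truth == "P") / sum(pred == "P")
    rec <- if (sum(truth == "P") == 0) 0 else
      sum(pred == "P" & truth == "P") / sum(truth == "P")
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    po <- acc
    pe <- (sum(pred == "P") * sum(truth == "P") +
           sum(pred == "E") * sum(truth == "E")) / total^2
    kap <- if (pe == 1) 0 else (po - pe) / (1 - pe)
    c(acc, prec, rec, f1, kap)
  }
  for (total in c(4L, 9L, 20L)) {
    combos <- expand.grid(tp = 0:total, tn = 0:total, fp = 0:total)
    combos <- combos[rowSums(combos) <= total, ]
    for (i in seq_len(nrow(combos))) {
      tp <- combos$tp[i]; tn <- combos$tn[i]; fp <- combos$fp[i]
      fn <- total - tp - tn - fp
      ref <- brute(tp, tn, fp, fn)
      m <- suppressWarnings(compute_metrics(confusion_matrix(tp, tn, fp, fn)))
      expect_equal(c(m$accuracy, m$precision, m$recall, m$f_measure,
                     m$cohens_kappa), ref, tolerance = 1e-12)
    }
  }
})

test_that("kappa vanishes for label-independent symmetric matrices", {
  for (k in c(1, 3, 7)) {
    m <- compute_metrics(confusion_matrix(k, k, k, k))
    expect_equal(m$cohens_kappa, 0)
  }
})

test_that("rank-based AUC behaves at the extremes and under chance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("ES", "ES", "PNES", "PNES")), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c("ES", "ES", "PNES", "PNES")), 0)
  set.seed(1)
  auc <- roc_auc(runif(2000), rep(c(0, 1), 1000))
  expect_lt(abs(auc - 0.5), 0.05)
  expect_error(roc_auc(runif(4), rep("ES", 4)), "both classes")
})

test_that("LOOCV never trains on the held-out subject's epochs", {
  # features encode the subject id; the fit function asserts the held-out
  # id is absent from its training matrix
  subjects <- lapply(1:4, function(i)
    list(subject_id = paste0("S", i),
         class_label = if (i %% 2 == 0) "ES" else "PNES",
         features = matrix(i, nrow = 5, ncol = 2)))
  seen <- new.env()
  # constant predictions make every subject ES -> degenerate precision,
  # which compute_metrics flags with its documented warning
  res <- suppressWarnings(run_loocv(
    subjects,
    fit_fun = function(X, y, fold) {
      ids <- unique(X[, 1])
      assign(paste0("fold", fold), ids, envir = seen)
      list(ids = ids)
    },
    predict_fun = function(fit, X) {
      expect_false(unique(X[, 1]) %in% fit$ids)
      rep(0.9, nrow(X))
    }))
  for (f in 1:4)
    expect_length(get(paste0("fold", f), envir = seen), 3L)
  expect_equal(nrow(res$per_subject), 4L)
})
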