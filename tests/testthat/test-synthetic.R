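test_that("cohort geometry and determinism contracts hold", {
  sp <- tiny_spec(seed = 7, subjects = 1L, epochs = 3L)
  coh <- generate_cohort(sp)
  expect_length(coh, 2L)
  expect_setequal(vapply(coh, `[[`, "", "class_label"), c("ES", "PNES"))

  sp2 <- tiny_spec(seed = 7, subjects = 2L, epochs = 3L)
  coh_a <- generate_cohort(sp2)
  coh_b <- generate_cohort(sp2)
  expect_identical(coh_a[[1]]$recording$data, coh_b[[1]]$recording$data)
  expect_identical(vapply(coh_a, `[[`, "", "subject_id"),
                   vapply(coh_b, `[[`, "", "subject_id"))

  rec <- coh_a[[1]]$recording
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 19L)
  expect_equal(ncol(rec$data), 3L * 2L * 256L)
  expect_equal(rec$channel_names, eeg_montage())
})

test_that("effect_size 0 gives bit-identical classes under the same seed", {
  sp <- cohort_spec(n_subjects_per_class = 1, epochs_per_subject = 3,
                    effect_size = 0, seed = 3)
  es <- generate_subject(sp, "ES", subject_seed = 99)
  pnes <- generate_subject(sp, "PNES", subject_seed = 99)
  expect_identical(es$data, pnes$data)

  # with delta > 0 only designated channels differ
  sp2 <- cohort_spec(n_subjects_per_class = 1, epochs_per_subject = 3,
                     effect_size = 1.5, seed = 3)
  es2 <- generate_subject(sp2, "ES", subject_seed = 99)
  pnes2 <- generate_subject(sp2, "PNES", subject_seed = 99)
  dch <- designated_channels()
  expect_identical(es2$data[-dch, ], pnes2$data[-dch, ])
  expect_true(all(rowSums(abs(es2$data[dch, ] - pnes2$data[dch, ])) > 0))
})

test_that("generated signal is band-limited to the working band", {
  sp <- tiny_spec(seed = 11, delta = 2, subjects = 1L, epochs = 30L)
  rec <- generate_subject(sp, "ES", subject_seed = 5)
  for (ch in c(1, 3)) {  # background-only and designated channel
    sp_est <- stats::spec.pgram(rec$data[ch, ], spans = 31, taper = 0,
                                plot = FALSE)
    f <- sp_est$freq * sp$sampling_rate
    hi <- mean(sp_est$spec[f > 40])
    inband <- mean(sp_est$spec[f > 2 & f < 30])
    expect_lt(hi / inband, 0.01)
  }
})

test_that("class effect raises ordinal complexity of designated channels", {
  # scaled version of the pre-build Monte-Carlo: one seed, delta = 2
  sp <- cohort_spec(n_subjects_per_class = 18, epochs_per_subject = 12,
                    effect_size = 2, seed = 41)
  coh <- generate_cohort(sp)
  cls <- vapply(coh, `[[`, "", "class_label")
  pe_des <- vapply(coh, function(su) {
    mean(vapply(designated_channels(), function(ch) {
      M <- matrix(su$recording$data[ch, ], nrow = 512)
      mean(pnesnet:::pe_cols(M, 3L, 1L))
    }, numeric(1)))
  }, numeric(1))
  w <- wilcoxon_rank_sum(pe_des[cls == "ES"], pe_des[cls == "PNES"])
  expect_gt(mean(pe_des[cls == "ES"]), mean(pe_des[cls == "PNES"]))
  expect_lt(w$p_value, 0.05)
})

test_that("continuous mode produces a masked 20-minute record", {
  sp <- cohort_spec(n_subjects_per_class = 1, epochs_per_subject = 10,
                    effect_size = 0, seed = 2, mode = "continuous")
  rec <- generate_subject(sp, "PNES", subject_seed = 8)
  expect_equal(ncol(rec$data), 20 * 60 * 256)
  expect_false(is.null(rec$artifact_mask))
  expect_gt(mean(rec$artifact_mask), 0.05)
  # mask is 2-s block aligned
  blocks <- matrix(rec$artifact_mask, nrow = 512)
  expect_true(all(colSums(blocks) %in% c(0L, 512L)))
})

test_that("cohort round-trips through the plain-text format", {
  dir <- withr::local_tempdir()
  sp <- tiny_spec(seed = 5, subjects = 1L, epochs = 2L)
  coh <- generate_cohort(sp)
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back[[1]]$recording$data, coh[[1]]$recording$data,
               tolerance = 1e-6)
  expect_equal(back[[2]]$class_label, coh[[2]]$class_label)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(epoch_seconds = 1.7, sampling_rate = 251),
               "integer")
  expect_error(cohort_spec(effect_size = -1), "nonnegative")
  expect_error(cohort_spec(n_subjects_per_class = 0), "at least one")
})
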