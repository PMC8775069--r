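make_rec <- function(signals, fs = 256) {
  eeg_recording(signals, fs, eeg_montage()[seq_len(nrow(signals))])
}

test_that("band-pass removes out-of-band tones and keeps mid-band tones", {
  fs <- 256
  t <- (0:(fs * 60 - 1)) / fs
  rec <- make_rec(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t)))
  out <- bandpass_filter(rec)
  expect_lt(sd(out$data[1, ]) / sd(rec$data[1, ]), 0.10)
  expect_lt(abs(sd(out$data[2, ]) / sd(rec$data[2, ]) - 1), 0.05)
})

test_that("filtered white noise has negligible power above 40 Hz", {
  set.seed(1)
  fs <- 256
  rec <- make_rec(matrix(rnorm(fs * 60), 1))
  out <- bandpass_filter(rec)
  est <- stats::spec.pgram(out$data[1, ], spans = 31, taper = 0, plot = FALSE)
  f <- est$freq * fs
  expect_lt(mean(est$spec[f > 40]) / mean(est$spec[f > 2 & f < 30]), 0.01)
})

test_that("filtering is idempotent up to tolerance for in-band content", {
  fs <- 256
  t <- (0:(fs * 30 - 1)) / fs
  rec <- make_rec(rbind(sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 4 * t)))
  once <- bandpass_filter(rec)
  twice <- bandpass_filter(once)
  expect_lt(abs(sd(twice$data[1, ]) / sd(once$data[1, ]) - 1), 0.01)
})

test_that("notch option attenuates 50 Hz when the band allows it", {
  fs <- 256
  t <- (0:(fs * 30 - 1)) / fs
  rec <- make_rec(rbind(sin(2 * pi * 50 * t)))
  out <- bandpass_filter(rec, low = 0.5, high = 60, notch50 = TRUE)
  ref <- bandpass_filter(rec, low = 0.5, high = 60, notch50 = FALSE)
  expect_lt(sd(out$data[1, ]), 0.3 * sd(ref$data[1, ]))
})

test_that("band edges are validated", {
  rec <- make_rec(matrix(rnorm(512), 1))
  expect_error(bandpass_filter(rec, high = 200), "Nyquist")
  expect_error(bandpass_filter(rec, low = 10, high = 5), "low < high")
})

test_that("downsampling halves 512 Hz records and preserves tones", {
  fs <- 512
  t <- (0:(fs * 1200 - 1)) / fs
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "Fp1")
  out <- downsample(rec, 256)
  expect_equal(out$sampling_rate, 256)
  expect_equal(ncol(out$data), 307200L)
  ideal <- sin(2 * pi * 10 * (0:(307200 - 1)) / 256)
  expect_gt(stats::cor(out$data[1, ], ideal), 0.999)

  # identity at target rate; non-integer factors rejected
  expect_identical(downsample(out, 256), out)
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("segmentation yields non-overlapping epochs and honours the mask", {
  fs <- 256
  rec <- eeg_recording(matrix(seq_len(fs * 1200), 1), fs, "Fp1")
  ep <- segment_epochs(rec, 2)
  expect_equal(dim(ep$epochs), c(600L, 1L, 512L))
  # concatenating epochs reproduces the retained record exactly
  expect_identical(as.numeric(t(ep$epochs[, 1, ])),
                   as.numeric(rec$data[1, seq_len(600 * 512)]))

  # mask covering 772 s in 2-s-aligned blocks leaves 214 retained epochs
  mask <- rep(FALSE, fs * 1200)
  bad_blocks <- seq_len(386)  # 386 * 2 s = 772 s
  for (b in bad_blocks) mask[((b - 1) * 512 + 1):(b * 512)] <- TRUE
  rec_m <- eeg_recording(matrix(rnorm(fs * 1200), 1), fs, "Fp1",
                         artifact_mask = mask)
  ep_m <- segment_epochs(rec_m, 2, max_epochs = 214)
  expect_equal(dim(ep_m$epochs)[1], 214L)
  expect_true(all(ep_m$epoch_index > 386 * 512))

  # 3 s record -> single epoch, remainder dropped
  rec3 <- eeg_recording(matrix(rnorm(3 * fs), 1), fs, "Fp1")
  expect_equal(dim(segment_epochs(rec3, 2)$epochs)[1], 1L)

  # fully masked record -> zero epochs
  rec0 <- eeg_recording(matrix(rnorm(fs * 4), 1), fs, "Fp1",
                        artifact_mask = rep(TRUE, fs * 4))
  expect_equal(dim(segment_epochs(rec0, 2)$epochs)[1], 0L)
})

test_that("recording text format round-trips with mask", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- eeg_recording(matrix(rnorm(38), 19), 256, eeg_montage(),
                       artifact_mask = c(TRUE, FALSE))
  write_recording_txt(rec, path)
  back <- read_recording_txt(path, 256)
  expect_equal(back$data, rec$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$artifact_mask, rec$artifact_mask)
})
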