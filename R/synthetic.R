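# Synthetic two-class resting-EEG cohort. The generative law is a stated
# surrogate, not a fitted model: per-channel 1/f^alpha Gaussian background
# (band-limited to 0.5-32 Hz) plus an amplitude-modulated alpha rhythm with
# posterior-dominant topography; subjects of the ES class additionally carry
# an intermittent ("burst") broadband component in six frontal/central/
# parietal channels whose amplitude scales with the effect size delta,
# raising those channels' ordinal complexity. delta = 0 makes the two classes
# bit-identical under the same seed.

#' Cohort specification for the synthetic EEG generator
#'
#' @param n_subjects_per_class Subjects per class (default 18).
#' @param epochs_per_subject Clean 2-s epochs per subject (default 214).
#' @param n_channels Number of channels, taken from the head of
#'   [eeg_montage()] (default 19).
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param epoch_seconds Epoch length in seconds (default 2);
#'   `epoch_seconds * sampling_rate` must be an integer.
#' @param effect_size Nonnegative class effect delta; the RMS of the injected
#'   broadband component in designated channels relative to the background RMS
#'   (0 = identical generative law for both classes; default 1).
#' @param seed Integer master seed.
#' @param mode `"epochs"` (default): emit exactly
#'   `epochs_per_subject * epoch_seconds` seconds of clean signal, epoch-ready;
#'   `"continuous"`: emit a 20-minute record with a random 2-s-aligned
#'   artifact mask, for exercising the preprocessing stage.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_class = 18L, epochs_per_subject = 214L,
                        n_channels = 19L, sampling_rate = 256,
                        epoch_seconds = 2, effect_size = 1, seed = 1L,
                        mode = c("epochs", "continuous")) {
  mode <- match.arg(mode)
  if (n_subjects_per_class < 1 || epochs_per_subject < 1)
    stop("need at least one subject and one epoch per subject")
  spe <- epoch_seconds * sampling_rate
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_seconds * sampling_rate must be an integer")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (n_channels < 1 || n_channels > 19)
    stop("n_channels must be in 1..19")
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 epoch_seconds = epoch_seconds,
                 effect_size = effect_size, seed = as.integer(seed),
                 mode = mode),
            class = "cohort_spec")
}

# Gaussian noise with a prescribed one-sided amplitude spectrum, unit RMS.
spectral_noise <- function(n, fs, shape_fun) {
  half <- n %/% 2
  f <- (1:half) * fs / n
  amp <- shape_fun(f)
  spec <- complex(real = rnorm(half), imaginary = rnorm(half)) * amp
  full <- complex(length.out = n)
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) full[half + 1] <- complex(real = rnorm(1) * amp[half])
  full[n:(n - half + 2)] <- Conj(full[2:half])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

band_shape <- function(low, high, exponent = 0) {
  function(f) ifelse(f >= low & f <= high, pmax(f, low)^(-exponent / 2), 0)
}

# Hard FFT-domain band-pass (used to re-limit modulated components).
bandlimit_fft <- function(x, fs, low, high) {
  n <- length(x)
  sp <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  sp[f < low | f > high] <- 0
  Re(stats::fft(sp, inverse = TRUE)) / n
}

# Relative alpha-rhythm weight per montage channel (posterior dominance).
alpha_topography <- function() {
  w <- c(Fp1 = 0.3, Fp2 = 0.3, F3 = 0.5, F4 = 0.5, C3 = 0.7, C4 = 0.7,
         P3 = 1.0, P4 = 1.0, O1 = 1.2, O2 = 1.2, F7 = 0.4, F8 = 0.4,
         T3 = 0.5, T4 = 0.5, T5 = 0.8, T6 = 0.8, Fz = 0.5, Cz = 0.7,
         Pz = 1.0)
  w
}

burst_gate <- function(n, fs, duty = 0.25, seg_seconds = 0.25) {
  seg <- max(1L, as.integer(round(seg_seconds * fs)))
  nseg <- ceiling(n / seg)
  act <- as.numeric(runif(nseg) < duty)
  g <- rep(act, each = seg)[seq_len(n)]
  # ~40 ms raised ramps so bursts do not introduce step discontinuities
  w <- max(3L, as.integer(round(0.04 * fs)))
  kern <- rep(1 / w, w)
  gs <- stats::filter(g, kern, sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  as.numeric(gs)
}

#' Generate one synthetic subject
#'
#' See [cohort_spec()] for the generative law. All randomness is drawn from
#' `subject_seed`; identical `(spec, class_label, subject_seed)` give
#' bit-identical recordings, and `effect_size = 0` makes the two class labels
#' produce identical data as well.
#'
#' @param spec A [cohort_spec()].
#' @param class_label `"ES"` or `"PNES"`.
#' @param subject_seed Integer seed for this subject.
#' @return An [eeg_recording()]; in `"continuous"` mode it carries a 2-s
#'   aligned artifact mask.
#' @export
generate_subject <- function(spec, class_label = c("ES", "PNES"),
                             subject_seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  class_label <- match.arg(class_label)
  fs <- spec$sampling_rate
  spe <- as.integer(round(spec$epoch_seconds * fs))
  n <- if (spec$mode == "epochs") spec$epochs_per_subject * spe
       else as.integer(20 * 60 * fs)
  set.seed(subject_seed)
  nch <- spec$n_channels
  chn <- eeg_montage()[seq_len(nch)]

  # subject-level nuisance parameters (both classes)
  slope <- runif(1, 0.85, 1.15)         # 1/f exponent
  alpha_f <- runif(1, 8.5, 11.5)        # individual alpha frequency, Hz
  alpha_base <- runif(1, 0.6, 1.4)      # subject alpha prominence
  rms_target <- 10 * runif(1, 0.9, 1.1) # microvolts
  # inter-subject background-complexity nuisance (all channels, both
  # classes): a broadband (0.5-32 Hz) and a slow (0.5-8 Hz) component with
  # subject-specific levels. They give channel-wise input PE realistic
  # between-subject overlap; magnitudes were fixed once by the pre-build
  # Monte-Carlo calibration described in the methods vignette.
  nuisance_amp <- runif(1, 0, 0.9)
  nuisance_slow_amp <- runif(1, 0, 1.5)

  topo <- alpha_topography()[chn]
  high_edge <- min(32, fs / 2 * 0.98)
  pink_shape <- band_shape(0.5, high_edge, exponent = 2 * slope)
  flat_shape <- band_shape(0.5, high_edge, exponent = 0)
  broad_shape <- band_shape(0.5, high_edge, exponent = 0)
  slow_shape <- band_shape(0.5, min(8, high_edge), exponent = 0)

  tt <- seq_len(n) / fs
  gate <- burst_gate(n, fs)             # drawn for both classes (determinism)
  dch <- intersect(designated_channels(), seq_len(nch))

  data <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    pink <- spectral_noise(n, fs, pink_shape)
    env <- 1 + 0.4 * spectral_noise(n, fs, band_shape(0.02, 0.5))
    env[env < 0] <- 0
    aw <- alpha_base * topo[ch] * runif(1, 0.7, 1.3)
    alpha <- aw * env * sin(2 * pi * alpha_f * tt + runif(1, 0, 2 * pi))
    bg <- pink + alpha / max(stats::sd(alpha), 1e-12) * aw * 0.7
    bg <- bg / stats::sd(bg) * rms_target
    broad <- spectral_noise(n, fs, broad_shape) * nuisance_amp * rms_target
    slow <- spectral_noise(n, fs, slow_shape) * nuisance_slow_amp * rms_target
    inj <- spectral_noise(n, fs, flat_shape)  # always drawn, maybe unused
    x <- bg + broad + slow
    if (ch %in% dch && class_label == "ES" && spec$effect_size > 0) {
      # band-limit AFTER envelope modulation so burst edges do not splatter
      # energy outside the working band
      burst <- bandlimit_fft(gate * inj, fs, 0.5, high_edge)
      brms <- stats::sd(burst)
      if (brms > 0)
        x <- x + burst / brms * (spec$effect_size * rms_target)
    }
    data[ch, ] <- x
  }
  mask <- NULL
  if (spec$mode == "continuous") {
    nblk <- n %/% spe
    bad <- runif(nblk) < 0.3
    mask <- rep(FALSE, n)
    for (b in which(bad)) mask[((b - 1) * spe + 1):(b * spe)] <- TRUE
  }
  eeg_recording(data, fs, chn, mask)
}

#' Generate the full two-class cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list with one element per subject (ES first, then PNES), each a
#'   list with `subject_id`, `class_label`, `seed` and `recording`.
#' @export
#' @examples
#' sp <- cohort_spec(n_subjects_per_class = 1, epochs_per_subject = 4)
#' length(generate_cohort(sp))  # 2 subjects
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  k <- 0L
  for (cls in c("ES", "PNES")) {
    for (i in seq_len(spec$n_subjects_per_class)) {
      k <- k + 1L
      sseed <- (spec$seed %% 100000L) * 20011L + k * 101L
      out[[k]] <- list(
        subject_id = sprintf("%s%02d", cls, i),
        class_label = cls,
        seed = sseed,
        recording = generate_subject(spec, cls, sseed))
    }
  }
  out
}

#' Segment every cohort subject into epochs and build sub-band tensors
#'
#' Convenience driver for the standard pipeline on a generated cohort:
#' optional band-pass filtering, optional downsampling, epoch segmentation
#' and DWT sub-band tensor construction.
#'
#' @param cohort A [generate_cohort()] result.
#' @param spec The matching [cohort_spec()].
#' @param bandpass If `TRUE`, apply [bandpass_filter()] first (off by default:
#'   the generator's output is band-limited by construction).
#' @param target_rate Optional rate for [downsample()].
#' @return A list per subject: `subject_id`, `class_label`, `tensor`
#'   (a [build_epoch_tensor()] result), `n_epochs`.
#' @export
cohort_tensors <- function(cohort, spec, bandpass = FALSE,
                           target_rate = NULL) {
  lapply(cohort, function(su) {
    rec <- su$recording
    if (bandpass) rec <- bandpass_filter(rec)
    if (!is.null(target_rate)) rec <- downsample(rec, target_rate)
    ep <- segment_epochs(rec, spec$epoch_seconds,
                         max_epochs = spec$epochs_per_subject)
    list(subject_id = su$subject_id, class_label = su$class_label,
         tensor = build_epoch_tensor(ep), n_epochs = dim(ep$epochs)[1])
  })
}

#' Write a cohort to disk as plain text
#'
#' One tab-separated recording file per subject plus `manifest.csv`
#' (`subject_id`, `class`, `file`, `seed`, `sampling_rate`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(su) {
    fn <- paste0(su$subject_id, ".tsv")
    write_recording_txt(su$recording, file.path(dir, fn))
    data.frame(subject_id = su$subject_id, class = su$class_label,
               file = fn, seed = su$seed,
               sampling_rate = su$recording$sampling_rate)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the recording files.
#' @return A cohort list as produced by [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    list(subject_id = manifest$subject_id[i],
         class_label = manifest$class[i],
         seed = manifest$seed[i],
         recording = read_recording_txt(file.path(dir, manifest$file[i]),
                                        manifest$sampling_rate[i]))
  })
}
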