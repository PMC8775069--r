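# Butterworth design via the standard zpk route: analog low-pass prototype,
# low-pass -> band-pass (or band-stop) transform, bilinear transform. Done
# in-package because the image ships no DSP package; validated in the test
# suite against frozen reference coefficients and pass/stop-band behaviour.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

butter_prototype_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Digital Butterworth band-pass/stop coefficients for band (low, high) Hz.
butter_band_coeffs <- function(order, low, high, fs, type = c("pass", "stop")) {
  type <- match.arg(type)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p <- butter_prototype_poles(order)
  if (type == "pass") {
    pb <- p * bw / 2
    poles <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
    zeros <- rep(0 + 0i, order)
    gain <- bw^order
  } else {
    poles <- c((bw / 2) / p + sqrt((bw / 2 / p)^2 - w0^2),
               (bw / 2) / p - sqrt((bw / 2 / p)^2 - w0^2))
    zeros <- rep(c(1i * w0, -1i * w0), order)
    gain <- 1  # DC gain renormalised exactly after the bilinear transform
  }
  # bilinear transform
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  kd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # pad zeros at z = -1 up to the pole count
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  if (type == "stop") {
    # normalise so the response at DC is exactly 1
    g0 <- sum(b) / sum(a)
    b <- b / g0
  }
  list(b = b, a = a)
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_vec <- function(b, a, x) {
  n <- length(x)
  pad <- 3 * (max(length(a), length(b)) - 1)
  if (n <= pad) stop("signal too short for zero-phase filtering")
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter an EEG recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel. The default 0.5-32 Hz band at order 3 is the working band of the
#' pipeline; zero-phase application avoids group delay, the standard choice
#' for offline EEG.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth order (per direction; default 3).
#' @param notch50 If `TRUE`, additionally apply a 48-52 Hz band-stop first,
#'   mirroring mains filtering in acquisition hardware. Off by default; the
#'   synthetic cohort is mains-free.
#' @return A filtered [eeg_recording()] at the same sampling rate.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 32, order = 3,
                            notch50 = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("`high` must be below the Nyquist frequency")
  data <- rec$data
  if (notch50) {
    if (fs / 2 > 52) {
      cf <- butter_band_coeffs(2, 48, 52, fs, "stop")
      for (i in seq_len(nrow(data)))
        data[i, ] <- filtfilt_vec(cf$b, cf$a, data[i, ])
    }
  }
  cf <- butter_band_coeffs(order, low, high, fs, "pass")
  for (i in seq_len(nrow(data)))
    data[i, ] <- filtfilt_vec(cf$b, cf$a, data[i, ])
  eeg_recording(data, fs, rec$channel_names, rec$artifact_mask)
}

#' Downsample a recording by an integer factor
#'
#' Decimates each channel to `target_rate`. The pipeline band-limits signals to
#' 32 Hz before decimation, so no extra anti-alias filter is applied here.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate Target sampling rate in Hz; `rec$sampling_rate` must be
#'   an integer multiple of it.
#' @return An [eeg_recording()] at `target_rate`. Already-at-rate input is
#'   returned unchanged.
#' @export
downsample <- function(rec, target_rate = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- rec$sampling_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("sampling_rate must be an integer multiple of target_rate")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  keep <- seq(1L, ncol(rec$data), by = factor)
  mask <- if (!is.null(rec$artifact_mask)) rec$artifact_mask[keep] else NULL
  eeg_recording(rec$data[, keep, drop = FALSE], target_rate,
                rec$channel_names, mask)
}

#' Partition a recording into non-overlapping clean epochs
#'
#' Cuts consecutive non-overlapping windows of `epoch_seconds` starting at
#' sample 1 (no jitter). Any window touching a masked (artifact) sample is
#' discarded wholesale; the trailing remainder is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_seconds Window length in seconds (default 2).
#' @param max_epochs Optional cap; the first `max_epochs` clean windows are
#'   kept.
#' @return An object of class `epoch_array`: list with `epochs` (an
#'   epochs x channels x samples array), `epoch_index` (1-based start sample
#'   of every retained window), `sampling_rate`, and `channel_names`. Zero
#'   clean windows yield an `epochs` array with first dimension 0.
#' @export
segment_epochs <- function(rec, epoch_seconds = 2, max_epochs = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- epoch_seconds * rec$sampling_rate
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_seconds * sampling_rate must be an integer")
  spe <- as.integer(round(spe))
  n <- ncol(rec$data)
  if (n < spe) stop("record shorter than one epoch")
  starts <- seq(1L, n - spe + 1L, by = spe)
  if (!is.null(rec$artifact_mask)) {
    clean <- vapply(starts, function(s)
      !any(rec$artifact_mask[s:(s + spe - 1L)]), logical(1))
    starts <- starts[clean]
  }
  if (!is.null(max_epochs)) starts <- utils::head(starts, max_epochs)
  eps <- array(0, dim = c(length(starts), nrow(rec$data), spe))
  for (i in seq_along(starts))
    eps[i, , ] <- rec$data[, starts[i]:(starts[i] + spe - 1L)]
  structure(list(epochs = eps, epoch_index = starts,
                 sampling_rate = rec$sampling_rate,
                 channel_names = rec$channel_names),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_array> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}
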