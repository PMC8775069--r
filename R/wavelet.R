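# Daubechies-4 analysis/synthesis filter bank. Coefficients are the standard
# published values (8 taps); symmetric half-point boundary extension matches
# the MATLAB wavedec default, so coefficient counts per level follow
# floor((n + 7) / 2).
db4_filters <- function() {
  dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
              0.030841381835560764, -0.18703481171909309,
              -0.027983769416859854, 0.6308807679298589,
              0.7148465705529157, 0.2303778133088965)
  n <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(n))
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
}

sym_extend <- function(x, p) {
  n <- length(x)
  c(x[p:1], x, x[n:(n - p + 1)])
}

dwt_step <- function(x, f) {
  flen <- length(f$dec_lo)
  xe <- sym_extend(x, flen - 1L)
  lo <- conv_valid(xe, f$dec_lo)
  hi <- conv_valid(xe, f$dec_hi)
  idx <- seq(2L, length(lo), by = 2L)
  list(a = lo[idx], d = hi[idx])
}

idwt_step <- function(ca, cd, f, out_len) {
  flen <- length(f$rec_lo)
  n <- length(ca)
  up_a <- up_d <- numeric(2L * n - 1L)
  up_a[seq(1L, 2L * n - 1L, by = 2L)] <- ca
  up_d[seq(1L, 2L * n - 1L, by = 2L)] <- cd
  pad <- numeric(flen - 1L)
  y <- conv_valid(c(pad, up_a, pad), f$rec_lo) +
       conv_valid(c(pad, up_d, pad), f$rec_hi)
  y <- y[(flen - 1L):(length(y) - flen + 2L)]
  y[seq_len(out_len)]
}

#' Multi-level discrete wavelet decomposition
#'
#' Mallat filter-bank cascade with the Daubechies-4 wavelet and symmetric
#' half-point boundary extension. The output mirrors MATLAB's `wavedec`
#' structure: a single concatenated coefficient vector `c` ordered
#' `[a5, d5, d4, d3, d2, d1]` and a bookkeeping vector `l` of per-block
#' lengths ending with the original signal length.
#'
#' @param signal Numeric vector (an epoch's single-channel samples).
#' @param wavelet Currently only `"db4"`.
#' @param level Decomposition depth (default 5).
#' @return Object of class `dwt_decomposition`: list with `c`, `l`, `wavelet`,
#'   `level`.
#' @export
#' @examples
#' d <- dwt_decompose(sin(2 * pi * 2 * (0:511) / 256))
#' d$l  # coefficient counts: a5, d5, ..., d1, then the signal length
dwt_decompose <- function(signal, wavelet = "db4", level = 5) {
  if (wavelet != "db4") stop("only the db4 wavelet is supported")
  if (level < 1) stop("level must be >= 1")
  f <- db4_filters()
  n <- length(signal)
  min_len <- 2^level  # conservative: every level must keep >= filter support
  if (n < length(f$dec_lo) * 2)
    stop("signal too short for the requested decomposition level")
  a <- signal
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- dwt_step(a, f)
    a <- st$a
    details[[j]] <- st$d
  }
  blocks <- c(list(a), rev(details))  # a5, d5, d4, d3, d2, d1
  structure(list(c = unlist(blocks),
                 l = c(vapply(blocks, length, integer(1)), n),
                 wavelet = wavelet, level = as.integer(level)),
            class = "dwt_decomposition")
}

# Split the concatenated coefficient vector into named blocks.
dwt_blocks <- function(dec) {
  nb <- length(dec$l) - 1L
  ends <- cumsum(dec$l[seq_len(nb)])
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- Map(function(s, e) dec$c[s:e], starts, ends)
  names(blocks) <- c(paste0("a", dec$level),
                     paste0("d", dec$level:1))
  blocks
}

# Inverse transform of a full (possibly zeroed) block list.
waverec_blocks <- function(blocks, dec) {
  f <- db4_filters()
  lvl <- dec$level
  lens <- dec$l
  a <- blocks[[paste0("a", lvl)]]
  for (j in lvl:1) {
    out_len <- if (j > 1) lens[lvl - j + 3L] else lens[length(lens)]
    a <- idwt_step(a, blocks[[paste0("d", j)]], f, out_len)
  }
  a
}

#' Reconstruct a single sub-band as a full-length signal
#'
#' Analogue of MATLAB's `wrcoef`: all coefficient blocks except the selected
#' one are zeroed and the inverse cascade is run, producing a time-domain
#' signal of the original length carrying only that sub-band's contribution.
#' Summing the six reconstructions `a5 + d5 + d4 + d3 + d2 + d1` recovers the
#' original signal to floating-point accuracy.
#'
#' @param dec A [dwt_decompose()] result.
#' @param kind `"detail"` or `"approximation"`.
#' @param level Sub-band level; for `"approximation"` it must equal the
#'   decomposition depth.
#' @return Numeric vector with the original signal length.
#' @export
reconstruct_subband <- function(dec, kind = c("detail", "approximation"),
                                level) {
  stopifnot(inherits(dec, "dwt_decomposition"))
  kind <- match.arg(kind)
  if (level < 1 || level > dec$level)
    stop("level outside the decomposition depth")
  if (kind == "approximation" && level != dec$level)
    stop("approximation is only stored at the deepest level")
  blocks <- dwt_blocks(dec)
  keep <- if (kind == "detail") paste0("d", level) else paste0("a", level)
  for (nm in names(blocks)) if (nm != keep) blocks[[nm]] <- 0 * blocks[[nm]]
  waverec_blocks(blocks, dec)
}

#' Nominal sub-band frequency edges
#'
#' Dyadic band edges of the five-level decomposition at a given sampling rate,
#' in the fixed band order `d1, d2, d3, d4, d5, a5`.
#'
#' @param fs Sampling rate in Hz (default 256).
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
subband_edges <- function(fs = 256) {
  ny <- fs / 2
  data.frame(band = c("d1", "d2", "d3", "d4", "d5", "a5"),
             low_hz = c(ny / 2, ny / 4, ny / 8, ny / 16, ny / 32, 0),
             high_hz = c(ny, ny / 2, ny / 4, ny / 8, ny / 16, ny / 32))
}

#' Build the sub-band tensor of an epoch array
#'
#' For every epoch and channel, the six reconstructed sub-band signals
#' (`d1..d5`, `a5`) are stacked along a fourth axis, yielding an
#' epochs x channels x samples x 6 array -- the CNN's input representation.
#'
#' @param epochs An `epoch_array` from [segment_epochs()] (or the generator);
#'   `samples` per epoch must be 512 for the default architecture but any
#'   length supported by the decomposition is accepted.
#' @param wavelet,level Passed to [dwt_decompose()].
#' @return Object of class `subband_tensor`: list with `values` (4-D array),
#'   `band_order`, `wavelet`, `level`, `sampling_rate`, `channel_names`.
#' @export
build_epoch_tensor <- function(epochs, wavelet = "db4", level = 5) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$epochs)
  ne <- d[1]; nch <- d[2]; ns <- d[3]
  if (wavelet != "db4") stop("only the db4 wavelet is supported")
  band_order <- c(paste0("d", seq_len(level)), paste0("a", level))
  f <- db4_filters()
  vals <- subband_tensor_cpp(epochs$epochs, dim(epochs$epochs),
                             as.integer(level), f$dec_lo, f$dec_hi,
                             f$rec_lo, f$rec_hi)
  structure(list(values = vals, band_order = band_order, wavelet = wavelet,
                 level = as.integer(level),
                 sampling_rate = epochs$sampling_rate,
                 channel_names = epochs$channel_names),
            class = "subband_tensor")
}

#' @export
print.subband_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<subband_tensor> %d epochs x %d channels x %d samples x %d bands (%s)\n",
              d[1], d[2], d[3], d[4], paste(x$band_order, collapse = ",")))
  invisible(x)
}
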