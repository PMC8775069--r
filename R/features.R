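#' Handcrafted sub-band features of one epoch
#'
#' Six statistics (Min, Max, Energy, Mean, Std, Skewness) of every
#' reconstructed sub-band signal of every channel. Energy is the sum of
#' squared samples; Std is the population standard deviation; Skewness is the
#' bias-uncorrected Fisher definition (0 for zero-variance signals). The flat
#' layout is channel-major, then band (`d1..d5, a5`), then statistic, giving
#' 19 x 6 x 6 = 684 entries for the default geometry.
#'
#' @param epoch_subbands A channels x samples x bands array (one epoch's slice
#'   of a [build_epoch_tensor()] tensor).
#' @return Named numeric vector of length `channels * bands * 6`.
#' @export
extract_features <- function(epoch_subbands) {
  d <- dim(epoch_subbands)
  if (length(d) != 3) stop("expected a channels x samples x bands array")
  nch <- d[1]; ns <- d[2]; nb <- d[3]
  # columns ordered band-major within channel after the aperm below
  M <- matrix(aperm(epoch_subbands, c(2, 3, 1)), nrow = ns)
  S <- col_stats6(M)  # 6 x (nb*nch), stats x (band within channel)
  out <- as.numeric(S)  # stat fastest, then band, then channel
  idx <- feature_index_map(nch, nb)
  names(out) <- paste(idx$channel, idx$band, idx$statistic, sep = ".")
  out
}

#' Flat-index layout of the handcrafted feature vector
#'
#' @param n_channels,n_bands Geometry (defaults 19 and 6).
#' @return Data frame mapping flat index to (channel, band, statistic).
#' @export
feature_index_map <- function(n_channels = 19L, n_bands = 6L) {
  stats <- c("Min", "Max", "Energy", "Mean", "Std", "Skewness")
  bands <- if (n_bands > 1L)
    c(paste0("d", seq_len(n_bands - 1L)), paste0("a", n_bands - 1L))
  else paste0("a", 0L)
  chn <- eeg_montage()[seq_len(n_channels)]
  data.frame(index = seq_len(n_channels * n_bands * 6L),
             channel = rep(chn, each = n_bands * 6L),
             band = rep(rep(bands, each = 6L), n_channels),
             statistic = rep(stats, n_channels * n_bands),
             stringsAsFactors = FALSE)
}

#' Feature matrix of a whole sub-band tensor
#'
#' @param tensor A [build_epoch_tensor()] result.
#' @return epochs x 684 numeric matrix (for the default geometry).
#' @export
tensor_features <- function(tensor) {
  X <- tensor_values(tensor)
  ne <- dim(X)[1]
  out <- matrix(0, ne, dim(X)[2] * dim(X)[4] * 6L)
  for (e in seq_len(ne)) out[e, ] <- extract_features(X[e, , , ])
  colnames(out) <- names(extract_features(X[1, , , , drop = TRUE]))
  out
}
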