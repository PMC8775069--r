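#' Permutation entropy of a time series
#'
#' Shannon entropy (base 2) of the distribution of ordinal patterns of
#' `order` consecutive values spaced `delay` samples apart (Bandt-Pompe).
#' Tied values are ranked by order of appearance (the earlier sample ranks
#' lower), a stable convention that keeps the measure deterministic on
#' rectified feature maps containing runs of equal values. The result lies in
#' `[0, log2(order!)]`; monotone series give exactly 0 and the value is
#' invariant under strictly increasing transformations of the series.
#'
#' @param x Numeric vector of length at least `(order - 1) * delay + 1`.
#' @param order Pattern length `n >= 2` (default 3).
#' @param delay Lag between pattern samples (default 1).
#' @param normalize If `TRUE`, divide by `log2(order!)`.
#' @return Permutation entropy in bits (or in `[0, 1]` when normalised).
#' @export
#' @examples
#' permutation_entropy(1:6)                      # 0: single ordinal pattern
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), order = 2)  # ~0.918
permutation_entropy <- function(x, order = 3, delay = 1, normalize = FALSE) {
  if (order < 2) stop("order must be >= 2")
  if (delay < 1) stop("delay must be >= 1")
  if (length(x) < (order - 1) * delay + 1)
    stop("series too short for the requested order and delay")
  pe <- pe_cols(matrix(as.numeric(x), ncol = 1), as.integer(order),
                as.integer(delay))[1]
  if (normalize) pe / log2(factorial(order)) else pe
}

# PE of every (epoch, channel, filter) time series of a 4-D activation array
# (epochs x channels x time x filters), averaged over filters then epochs:
# returns one value per channel.
channel_pe <- function(maps, order, delay) {
  d <- dim(maps)
  M <- matrix(aperm(maps, c(3, 1, 2, 4)), nrow = d[3])
  pe <- pe_cols(M, as.integer(order), as.integer(delay))
  # columns ordered epoch fastest, then channel, then filter
  arr <- array(pe, dim = c(d[1], d[2], d[4]))
  apply(arr, 2, mean)
}

#' Per-subject, per-channel permutation entropy of input and feature maps
#'
#' For each subject and each requested layer, the PE of every time series in
#' the layer's activation array is computed along the temporal axis, averaged
#' over filters (over sub-bands for the input layer) and then over the
#' subject's epochs, giving one value per EEG channel row.
#'
#' @param model A trained `cnn_model`.
#' @param tensors Cohort tensors from [cohort_tensors()].
#' @param layers Subset of `c("input", "Conv1", "Conv2")`.
#' @param order,delay PE parameters (defaults 3 and 1).
#' @return Data frame (`pe_table`) with columns `subject_id`, `class`,
#'   `layer`, `channel` (index), `channel_name`, `pe` (bits); one row per
#'   (subject, layer, channel).
#' @export
layer_pe_table <- function(model, tensors,
                           layers = c("input", "Conv1", "Conv2"),
                           order = 3, delay = 1) {
  layers <- match.arg(layers, several.ok = TRUE)
  conv_layers <- intersect(c("Conv1", "Conv2"), layers)
  if (length(conv_layers) && !model$trained)
    stop("model has not been trained")
  pa <- if (length(conv_layers)) cnn_get_params(model) else NULL
  rows <- list()
  for (su in tensors) {
    X <- su$tensor$values
    ne <- dim(X)[1]
    nch <- dim(X)[2]
    pe_by_layer <- list()
    if ("input" %in% layers) {
      pe_by_layer$input <- channel_pe(X, order, delay)
    }
    if (length(conv_layers)) {
      # one chunked forward pass serves both convolutional layers
      cnn_stack_load(X, dim(X), model$spec$input_gain)
      acc <- lapply(conv_layers, function(ly) numeric(nch))
      names(acc) <- conv_layers
      chunk <- 128L
      for (s in seq(1L, ne, by = chunk)) {
        sl <- s:min(s + chunk - 1L, ne)
        cnn_stack_forward(as.integer(sl),
                          pa$W1, dim(pa$W1), pa$b1,
                          pa$W2, dim(pa$W2), pa$b2,
                          pa$Wd1, pa$bd1, 2L, 2L)
        for (ly in conv_layers) {
          pe_bh <- cnn_stack_pe(ly, as.integer(order), as.integer(delay))
          acc[[ly]] <- acc[[ly]] + colSums(pe_bh)
        }
      }
      for (ly in conv_layers) pe_by_layer[[ly]] <- acc[[ly]] / ne
    }
    for (ly in layers) {
      pe <- pe_by_layer[[ly]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = su$subject_id, class = su$class_label, layer = ly,
        channel = seq_along(pe),
        channel_name = su$tensor$channel_names[seq_along(pe)],
        pe = pe, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pe_table", class(out))
  out
}

#' Per-channel class comparison of PE values
#'
#' Wilcoxon rank-sum test of ES vs. PNES subject PE values for every channel
#' of one layer. No multiple-testing correction by default, matching the
#' per-channel reporting convention; set `bonferroni = TRUE` to multiply the
#' p-values by the channel count.
#'
#' @param pe_table A [layer_pe_table()] result.
#' @param layer Layer to test.
#' @param bonferroni Apply Bonferroni correction.
#' @return Data frame: `channel`, `channel_name`, `statistic`, `p_value`,
#'   `mean_es`, `mean_pnes`.
#' @export
channel_pe_tests <- function(pe_table, layer, bonferroni = FALSE) {
  tab <- pe_table[pe_table$layer == layer, ]
  chans <- sort(unique(tab$channel))
  rows <- lapply(chans, function(ch) {
    a <- tab$pe[tab$channel == ch & tab$class == "ES"]
    b <- tab$pe[tab$channel == ch & tab$class == "PNES"]
    w <- wilcoxon_rank_sum(a, b)
    data.frame(channel = ch,
               channel_name = tab$channel_name[tab$channel == ch][1],
               statistic = w$statistic, p_value = w$p_value,
               mean_es = mean(a), mean_pnes = mean(b))
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * length(chans))
  out
}

#' Count of class-separating channels per layer
#'
#' The depth-separability summary: how many channels show a significant
#' (p < `alpha`) ES vs. PNES difference in PE at each layer. In a cohort with
#' a sufficiently strong class effect this count is expected to be
#' non-decreasing from the input to the deeper convolutional layers.
#'
#' @param pe_table A [layer_pe_table()] result.
#' @param alpha Significance level (default 0.05).
#' @return Named integer vector, one entry per layer present in the table.
#' @export
depth_separability <- function(pe_table, alpha = 0.05) {
  layers <- intersect(c("input", "Conv1", "Conv2"), unique(pe_table$layer))
  vapply(stats::setNames(layers, layers), function(ly) {
    tests <- channel_pe_tests(pe_table, ly)
    sum(tests$p_value < alpha)
  }, integer(1))
}
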