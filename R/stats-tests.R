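#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test of the null that both samples are
#' drawn from the same distribution. For moderate tie-free samples
#' (`length(a) * length(b) <= 10000`) the exact null distribution of the U
#' statistic is used; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @return Object of class `stat_test`: `test`, `statistic` (Mann-Whitney U
#'   of `a`), `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && m * n <= 10000) {
    p <- if (u > m * n / 2) 2 * stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
         else 2 * stats::pwilcox(u, m, n)
    method <- "exact"
  } else {
    N <- m + n
    mu <- m * n / 2
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- u - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(max(sigma2, .Machine$double.eps))
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(test = "wilcoxon_rank_sum", statistic = u,
                 p_value = min(p, 1), method = method),
            class = "stat_test")
}

#' Friedman test with Nemenyi post hoc comparisons
#'
#' Friedman's rank test across classifiers (columns) measured on the same
#' blocks (rows), with average ranks on ties and the standard tie-corrected
#' chi-square statistic; followed by the Nemenyi all-pairs test based on the
#' studentized range distribution.
#'
#' @param accuracy_matrix Numeric matrix, blocks x classifiers (at least 2 of
#'   each). Column names label the classifiers.
#' @return Object of class `stat_test`: `statistic` (chi-square), `p_value`,
#'   `df`, `mean_ranks`, and `nemenyi` (symmetric matrix of pairwise
#'   p-values).
#' @export
friedman_nemenyi <- function(accuracy_matrix) {
  X <- as.matrix(accuracy_matrix)
  n <- nrow(X); k <- ncol(X)
  if (k < 2) stop("need at least two classifiers")
  if (n < 2) stop("need at least two blocks")
  R <- t(apply(X, 1, rank))
  Rj <- colSums(R)
  # tie correction per block (Conover / R's friedman.test)
  ties_term <- sum(apply(X, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - ties_term / (k - 1)
  stat <- if (den <= 0) 0 else num / den
  p <- if (den <= 0) 1 else stats::pchisq(stat, df = k - 1,
                                          lower.tail = FALSE)
  mean_ranks <- Rj / n
  se <- sqrt(k * (k + 1) / (6 * n))
  q <- abs(outer(mean_ranks, mean_ranks, "-")) / se
  nem <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  diag(nem) <- 1
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("clf", seq_len(k))
  dimnames(nem) <- list(cn, cn)
  names(mean_ranks) <- cn
  structure(list(test = "friedman", statistic = stat, p_value = p,
                 df = k - 1, mean_ranks = mean_ranks, nemenyi = nem),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}
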