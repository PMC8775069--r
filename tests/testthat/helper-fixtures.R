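# Shared fixtures: everything is generated in code, sized for speed.

tiny_spec <- function(seed = 1, delta = 2, subjects = 2L, epochs = 4L) {
  cohort_spec(n_subjects_per_class = subjects, epochs_per_subject = epochs,
              effect_size = delta, seed = seed)
}

tiny_cohort_tensors <- function(seed = 1, delta = 2, subjects = 2L,
                                epochs = 4L) {
  sp <- tiny_spec(seed, delta, subjects, epochs)
  cohort_tensors(generate_cohort(sp), sp)
}

# stack a cohort into (X, y) for direct CNN training
cohort_xy <- function(tens) {
  X <- pnesnet:::bind_epochs(lapply(tens, pnesnet:::subject_X))
  y <- unlist(lapply(tens, function(su)
    rep(as.integer(su$class_label == "ES"), su$n_epochs)))
  list(X = X, y = y)
}

# brute-force ordinal-pattern PE oracle (independent of the C++ path):
# ranks with ties broken by order of appearance
pe_oracle <- function(x, order = 3, delay = 1) {
  n <- length(x)
  nwin <- n - (order - 1) * delay
  pats <- vapply(seq_len(nwin), function(i) {
    v <- x[i + (0:(order - 1)) * delay]
    paste(rank(v, ties.method = "first"), collapse = "")
  }, character(1))
  p <- table(pats) / nwin
  -sum(p * log2(p))
}

# exhaustive two-sided rank-sum permutation p-value (small n)
wilcox_perm_oracle <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pooled), m)
  mn <- length(a) * length(b)
  stats <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(abs(stats - mn / 2) >= abs(obs - mn / 2) - 1e-9)
}
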