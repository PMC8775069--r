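# Binary soft-margin SVM with RBF kernel, trained by the simplified SMO
# algorithm on a cached kernel matrix. Implemented in-package because the
# image ships no kernel-SVM package; adequate for the cohort sizes used here
# (the full kernel matrix is materialised).

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  exp(-gamma * (outer(an, bn, "+") - 2 * tcrossprod(A, B)))
}

svm_rbf_fit <- function(X, y01, gamma = 0.001, C = 1, tol = 1e-3,
                        max_passes = 5, max_iter = 200, seed = 1L) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  set.seed(seed)
  passes <- 0L
  iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    Fcache <- as.numeric(crossprod(K, alpha * y)) + b  # f(x_i) for all i
    for (i in seq_len(n)) {
      Ei <- Fcache[i] - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample(seq_len(n)[-i], 1)
        Ej <- Fcache[j] - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L == H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b_old <- b
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        Fcache <- Fcache + y[i] * (ai - ai_old) * K[, i] +
          y[j] * (aj - aj_old) * K[, j] + (b - b_old)
        alpha[i] <- ai; alpha[j] <- aj
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iter <- iter + 1L
  }
  sv <- alpha > 1e-8
  list(X = X[sv, , drop = FALSE], coef = (alpha * y)[sv], b = b,
       gamma = gamma)
}

svm_rbf_decision <- function(fit, X) {
  if (nrow(fit$X) == 0) return(rep(fit$b, nrow(X)))
  as.numeric(rbf_kernel(X, fit$X, fit$gamma) %*% fit$coef + fit$b)
}
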