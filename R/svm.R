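# Minimal deterministic C-SVC via sequential minimal optimization, for
# the handful-of-samples leave-one-out setting this package targets.
# Second working-set index is chosen by maximal |E_i - E_j|, so the
# solver has no random component.

svm_kernel <- function(A, B, kernel, gamma, degree = 3, coef0 = 1) {
  G <- A %*% t(B)
  switch(kernel,
         linear = G,
         poly = (coef0 + G)^degree,
         rbf = {
           an <- rowSums(A^2); bn <- rowSums(B^2)
           exp(-gamma * (outer(an, bn, "+") - 2 * G))
         },
         stop("unknown kernel"))
}

svm_fit <- function(X, y, kernel = "linear", C = 1, gamma = NULL,
                    degree = 3, coef0 = 1, tol = 1e-3, max_passes = 10,
                    max_iter = 5000) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)))
  n <- nrow(X)
  if (is.null(gamma)) {
    v <- mean(apply(X, 2, stats::var))
    gamma <- 1 / (ncol(X) * max(v, 1e-12))
  }
  K <- svm_kernel(X, X, kernel, gamma, degree, coef0)
  alpha <- numeric(n); b <- 0
  passes <- 0; iter <- 0
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    E <- fcache() - y
    for (i in seq_len(n)) {
      Ei <- E[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(Ei - E[-i]))
        j <- seq_len(n)[-i][j]
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        E <- fcache() - y
        changed <- changed + 1
      }
      iter <- iter + 1
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  list(X = X, y = y, alpha = alpha, b = b, kernel = kernel,
       gamma = gamma, degree = degree, coef0 = coef0)
}

svm_decision <- function(model, Xnew) {
  Kn <- svm_kernel(as.matrix(Xnew), model$X, model$kernel, model$gamma,
                   model$degree, model$coef0)
  as.numeric(Kn %*% (model$alpha * model$y)) + model$b
}
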