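# Independent oracles used to validate the package's estimators.

# Naive double-loop implementation of the weighted-sampling KL decomposition:
# O(M^2 * D) with explicit loops, no shared code with the package's kernel.
kl_naive <- function(z, mu, lv, N) {
  M <- nrow(z)
  D <- ncol(z)
  W <- matrix(log((N - 1) / (N * (M - 1))), M, M)
  diag(W) <- -log(N)
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  S <- numeric(M)
  Sd <- matrix(0, M, D)
  diagL <- numeric(M)
  logp <- numeric(M)
  for (i in seq_len(M)) {
    ld <- matrix(0, M, D)
    for (j in seq_len(M)) {
      for (d in seq_len(D)) {
        ld[j, d] <- stats::dnorm(z[i, d], mu[j, d], exp(0.5 * lv[j, d]),
                                 log = TRUE)
      }
    }
    l <- rowSums(ld)
    S[i] <- lse(l + W[i, ])
    for (d in seq_len(D)) Sd[i, d] <- lse(ld[, d] + W[i, ])
    diagL[i] <- l[i]
    logp[i] <- sum(stats::dnorm(z[i, ], 0, 1, log = TRUE))
  }
  list(
    mi = mean(diagL - S),
    tc = mean(S - rowSums(Sd)),
    dwkl = mean(rowSums(Sd) - logp)
  )
}

# Reference one-way ANOVA F via stats::aov, one latent dimension at a time.
ref_anova_f <- function(groups) {
  D <- ncol(groups[[1]])
  ns <- vapply(groups, nrow, 1L)
  fac <- factor(rep(seq_along(groups), ns))
  vapply(seq_len(D), function(d) {
    y <- unlist(lapply(groups, function(g) g[, d]))
    summary(stats::aov(y ~ fac))[[1]][["F value"]][1]
  }, 1.0)
}

# Central-difference gradient of a scalar function of a matrix argument.
numeric_grad <- function(f, X, eps = 1e-6) {
  out <- X * 0
  for (i in seq_along(X)) {
    Xp <- X
    Xm <- X
    Xp[i] <- X[i] + eps
    Xm[i] <- X[i] - eps
    out[i] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  out
}
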