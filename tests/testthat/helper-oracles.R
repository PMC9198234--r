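# Independent oracles, deliberately written as naive direct translations of
# the defining formulas rather than reusing package internals.

# Exhaustive scan of the minimum-error criterion: for every candidate split,
# recompute the two-class weights/means/variances by plain summation and
# evaluate J; returns the bin-center of the best (lowest, on ties) split.
ki_threshold_bruteforce <- function(bin_edges, counts) {
  B <- length(counts)
  centers <- (bin_edges[-1] + bin_edges[-(B + 1)]) / 2
  bw <- bin_edges[2] - bin_edges[1]
  vfloor <- bw^2 / 12
  best_J <- Inf
  best_t <- NA
  n <- sum(counts)
  for (t in 1:(B - 1)) {
    idx1 <- 1:t; idx2 <- (t + 1):B
    n1 <- sum(counts[idx1]); n2 <- sum(counts[idx2])
    if (n1 == 0 || n2 == 0) next
    P1 <- n1 / n; P2 <- n2 / n
    m1 <- sum(counts[idx1] * centers[idx1]) / n1
    m2 <- sum(counts[idx2] * centers[idx2]) / n2
    v1 <- max(sum(counts[idx1] * (centers[idx1] - m1)^2) / n1, vfloor)
    v2 <- max(sum(counts[idx2] * (centers[idx2] - m2)^2) / n2, vfloor)
    J <- 1 + 2 * (P1 * log(sqrt(v1)) + P2 * log(sqrt(v2))) -
      2 * (P1 * log(P1) + P2 * log(P2))
    if (J < best_J - 1e-12) {
      best_J <- J
      best_t <- centers[t]
    }
  }
  best_t
}

# Pooled-variance two-sample t from the textbook formulas.
student_t_direct <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tstat, p = 2 * pt(-abs(tstat), df))
}

# Welch t with Welch-Satterthwaite degrees of freedom.
welch_t_direct <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  se2 <- var(a) / n1 + var(b) / n2
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n2)^2 / (n2 - 1))
  list(t = tstat, p = 2 * pt(-abs(tstat), df), df = df)
}

# Two-sided permutation p-value for a difference in means.
permutation_p <- function(a, b, n_perm = 1e5, seed = 99L) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  n1 <- length(a)
  withr::with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), n1)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-15) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

# Strain energy of a displacement state, by direct quadrature over elements:
# 0.5 * sum_e V_e * eps:C:eps with eps from finite differences of the
# displacement field is avoided; instead energy is evaluated from the
# closed-form constant strain of each tet computed independently via lm().
strain_energy_direct <- function(mesh, u, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  U <- matrix(u, ncol = 3, byrow = TRUE)
  total <- 0
  for (e in seq_len(nrow(mesh$elements))) {
    nid <- mesh$elements[e, ]
    X <- mesh$nodes[nid, ]
    V <- abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))) / 6
    # displacement gradient from a linear fit u_i = a + g . x per component
    H <- matrix(0, 3, 3)
    for (i in 1:3) {
      fit <- lm.fit(cbind(1, X), U[nid, i])
      H[i, ] <- fit$coefficients[2:4]
    }
    eps <- (H + t(H)) / 2
    total <- total + V * (0.5 * lam * sum(diag(eps))^2 + mu * sum(eps^2))
  }
  total
}
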