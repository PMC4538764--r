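# Independent GLS oracle for the variance of the treatment effect on
# cluster-period means: per-cluster J x J covariance
# sigma2_a * ones + (sigma2_e / K) * identity, fixed effects
# {intercept, J-1 time indicators, treatment}. Computed directly from the
# inverse Fisher information, with no reference to the closed-form formula.
gls_treatment_variance <- function(X, sigma2_e, sigma2_a, K) {
  I <- nrow(X); J <- ncol(X)
  Sigma <- sigma2_a * matrix(1, J, J) + diag(sigma2_e / K, J)
  Sigma_inv <- solve(Sigma)
  p <- 1L + (J - 1L) + 1L
  info <- matrix(0, p, p)
  time_dummies <- cbind(0, diag(J - 1L))  # times 2..J
  for (i in seq_len(I)) {
    Zi <- cbind(1, t(time_dummies), X[i, ])
    info <- info + t(Zi) %*% Sigma_inv %*% Zi
  }
  solve(info)[p, p]
}

# Random valid stepped wedge design for property tests. At least two
# distinct crossover times are used, so the treatment effect is always
# identified alongside the time effects.
random_swt_design <- function(max_clusters = 12, max_times = 8,
                              cluster_size = NULL) {
  J <- sample(3:max_times, 1)
  I <- sample(2:max_clusters, 1)
  repeat {
    alloc <- tabulate(sample.int(J - 1L, I, replace = TRUE), nbins = J - 1L)
    if (sum(alloc > 0L) >= 2L) break
  }
  K <- if (is.null(cluster_size)) sample(1:30, 1) else cluster_size
  swt_design(alloc, J, K)
}

# All weak compositions of n into k non-negative parts.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- lapply(0:n, function(first)
    cbind(first, compositions(n - first, k - 1L)))
  do.call(rbind, out)
}
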