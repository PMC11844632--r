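# Independent brute-force oracles. These deliberately use naive linear
# algebra (explicit inverse / determinant) and direct enumeration, not the
# package's Cholesky code paths.

# GP posterior at query points from explicit matrices
oracle_gp_posterior <- function(K_train, K_cross, k_self_diag, y) {
  Ki <- solve(K_train)
  mean <- as.numeric(K_cross %*% Ki %*% y)
  var <- k_self_diag - diag(K_cross %*% Ki %*% t(K_cross))
  list(mean = mean, var = var)
}

# log marginal likelihood from explicit inverse and determinant
oracle_lml <- function(K, y) {
  n <- length(y)
  as.numeric(-0.5 * t(y) %*% solve(K) %*% y -
             0.5 * determinant(K, logarithm = TRUE)$modulus -
             0.5 * n * log(2 * pi))
}

# exact two-sided signed-rank test by enumerating all 2^n sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  p <- mean(abs(Vs - mu) >= abs(v - mu) - 1e-9)
  list(statistic = v, p.value = p)
}

# a small fully measured map with hand-set thresholds on a custom ladder,
# for tests that need exact control over values
hand_map <- function(thresholds, n_rows = 1, n_cols = length(thresholds),
                     ladder = amplitude_ladder(min(thresholds) / 2,
                                               max(thresholds) * 2, 10)) {
  grid <- electrode_grid(n_rows, n_cols)
  threshold_map(grid, thresholds, ladder = ladder, label = "hand")
}
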