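# Independent oracles and tiny fixture builders. These deliberately avoid the
# package's own code paths: OLS via explicit normal equations, partial
# correlations via the residual-regression definition, spectral radius via
# power iteration.

# OLS coefficients by normal equations (intercept NOT added automatically)
oracle_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# partial correlation of columns i and j given all remaining columns,
# by correlating the residuals of the two one-on-rest regressions
oracle_partial_cor <- function(M, i, j) {
  rest <- setdiff(seq_len(ncol(M)), c(i, j))
  res_of <- function(col) {
    if (!length(rest)) return(M[, col] - mean(M[, col]))
    D <- cbind(1, M[, rest, drop = FALSE])
    M[, col] - D %*% solve(crossprod(D), crossprod(D, M[, col]))
  }
  drop(cor(drop(res_of(i)), drop(res_of(j))))
}

oracle_spectral_radius <- function(M, iters = 2000) {
  # power iteration on M'M gives the largest singular value; for the
  # (possibly complex) eigenvalue modulus use the eigen-free bound via
  # repeated squaring of the matrix norm ratio
  v <- rep(1, ncol(M)) / sqrt(ncol(M))
  lam <- NA_real_
  for (i in seq_len(iters)) {
    w <- M %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lam <- nw
  }
  lam
}

# small complete panel with reproducible Gaussian values (continuous scale)
toy_panel <- function(T = 40, items = c("worried", "irritable", "down"),
                      seed = 42, id = "p1") {
  valence <- setNames(rep("negative", length(items)), items)
  set.seed(seed)
  m <- matrix(rnorm(T * length(items)), T, length(items),
              dimnames = list(NULL, items))
  ema_panel(id, m, valence, scale = "continuous")
}

# panel simulated from a known VAR(1), full item set recoverable
sim_panel <- function(n_items = 5, T = 500, gamma_frac = 0.8, seed = 7,
                      scale = "continuous", missing_rate = 0,
                      base_coupling = 0.05) {
  spec <- make_spec(n_items = n_items, base_coupling = base_coupling,
                    seed = seed, scale = scale, missing_rate = missing_rate)
  g <- gamma_frac * spec$gamma_range[2]
  list(panel = simulate_participant(spec, g, T = T, seed = seed + 1),
       A = emanet:::lag_matrix(spec, g), spec = spec, gamma = g)
}
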