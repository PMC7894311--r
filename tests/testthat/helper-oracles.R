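# Independent oracles used across test files.

# Brute-force root of theta z^2 - (x1+x2) z + x1 x2 = 0: locate the first
# sign change of the polynomial on a dense grid over [0, min(x1,x2)] and
# refine with uniroot. Uses only polynomial evaluation, independent of the
# closed-form solution under test.
root_oracle <- function(theta, x1, x2, n_grid = 1000) {
  q <- function(z) theta * z^2 - (x1 + x2) * z + x1 * x2
  zs <- seq(0, min(x1, x2), length.out = n_grid)
  v <- q(zs)
  k <- which(v[-1] <= 0 & v[-length(v)] > 0)[1]
  if (is.na(k)) return(min(x1, x2))  # root at the grid end (theta = 1)
  stats::uniroot(q, c(zs[k], zs[k + 1]), tol = 1e-13)$root
}

# Dense grid search for the coupled-Ci solution: scan the supply/demand
# residual over a fine Ci grid and return the Ci at the sign change.
coupled_oracle <- function(env, params, config, stomatal, n_grid = 1e5) {
  ca_pa <- co2_to_pa(env$ca, env$pressure)
  ci <- seq(1e-3, ca_pa * 1.05 + 2, length.out = n_grid)
  r <- assimilation_at_ci(ci, env, params, config)
  gs <- medlyn_gs(r$a_net, env$ca, env$vpd, stomatal)
  resid <- (env$ca - 1.6 * r$a_net / gs) * env$pressure * 1e-3 - ci
  k <- which(diff(sign(resid)) < 0)[1]
  mean(ci[k + 0:1])
}

central_param_list <- function(n = 1) {
  rng <- param_ranges()
  out <- as.list(rng$central)
  names(out) <- rng$name
  out
}
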