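#' Priors for A-Ci curve fitting
#'
#' Independent uniform priors for the sampled parameters: `vcmax25` in
#' [100, 200] umol CO2 m-2 s-1, `jmax25` in [70, 400] umol e m-2 s-1,
#' `theta_cj` in [0.9, 1.0], and the residual scale `sigma` in
#' (0, `sigma_max`]. `sigma` is a sampled nuisance parameter: the iid
#' Gaussian error model leaves it unknown, so it is estimated jointly.
#'
#' @param vcmax,jmax,theta_cj Length-2 bounds.
#' @param sigma_max Upper bound of the residual scale (umol CO2 m-2 s-1).
#' @param sigma_min Small positive lower bound keeping the likelihood
#'   finite on noise-free data.
#' @return A `prior_set` list with `lower` and `upper` named vectors.
#' @export
aci_priors <- function(vcmax = c(100, 200), jmax = c(70, 400),
                       theta_cj = c(0.9, 1.0), sigma_max = 10,
                       sigma_min = 1e-3) {
  lower <- c(vcmax25 = vcmax[1], jmax25 = jmax[1], theta_cj = theta_cj[1],
             sigma = sigma_min)
  upper <- c(vcmax25 = vcmax[2], jmax25 = jmax[2], theta_cj = theta_cj[2],
             sigma = sigma_max)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  structure(list(lower = lower, upper = upper), class = "prior_set")
}

# Demand-side prediction of A at the measured Ci for the fitted model
# family: carboxylation + RuBP-regeneration limitation smoothed with
# theta_cj (TPU excluded), non-rectangular light response with theta_j
# fixed. The measured Ci bypasses the stomatal solve entirely.
aci_predict <- function(vcmax25, jmax25, theta_cj, ci_pa, irradiance,
                        fixed = photo_params()) {
  alpha_i <- 0.5 * (1 - fixed$f_loss)
  aai <- fixed$absorptance_a * alpha_i * irradiance
  j <- smaller_root(fixed$theta_j, aai, jmax25)
  gstar <- fixed$ko_kc_ratio * fixed$kc_half * 21 / (2 * fixed$ko_half)
  km <- fixed$kc_half * (1 + 21 / fixed$ko_half)
  ac <- vcmax25 * ci_pa / (ci_pa + km)
  aj <- (j / 4) * ci_pa / (ci_pa + 2 * gstar)
  ag <- smaller_root(theta_cj, ac, aj)
  ag * (1 - gstar / ci_pa) - fixed$b_rv * vcmax25
}

#' Gaussian iid log-likelihood of an A-Ci curve
#'
#' Log-density of the observed assimilation rates given demand-side
#' predictions at each record's measured Ci, under independent identically
#' distributed Gaussian residuals with scale `sigma`. Because predictions
#' are made at measured Ci, the likelihood is invariant to any stomatal
#' parameters.
#'
#' @param theta Named vector `vcmax25`, `jmax25`, `theta_cj`, `sigma`.
#' @param curve An `aci_curve` (columns `ci_pa`, `a_umol_m2_s`, `qin`).
#' @param fixed A [photo_params()] supplying the non-sampled constants
#'   (kinetics, absorptance, `theta_j`, respiration scaling).
#' @return Log-likelihood; `-Inf` if the forward model fails.
#' @export
aci_loglik <- function(theta, curve, fixed = photo_params()) {
  irr <- if ("qin" %in% names(curve)) curve$qin else 2000
  pred <- aci_predict(theta[["vcmax25"]], theta[["jmax25"]],
                      theta[["theta_cj"]], curve$ci_pa, irr, fixed)
  if (any(!is.finite(pred))) return(-Inf)
  r <- curve$a_umol_m2_s - pred
  n <- length(r)
  -0.5 * n * log(2 * pi * theta[["sigma"]]^2) -
    sum(r * r) / (2 * theta[["sigma"]]^2)
}

#' Truncate the TPU-affected high-CO2 region of a curve
#'
#' Detects the first sustained decline of A with increasing Ca (a run of
#' `k` consecutive decreases of the running-mean-smoothed rate) and removes
#' all records above its onset. Curves without such a decline are returned
#' unchanged.
#'
#' @param curve An `aci_curve`.
#' @param k Length of the decreasing run that counts as sustained.
#' @param window Running-mean window (records) used before differencing.
#' @return The (possibly truncated) curve; attribute `"ca_cutoff"` gives
#'   the detected onset (umol/mol) or `NA`.
#' @export
truncate_tpu_region <- function(curve, k = 5, window = 5) {
  ord <- order(curve$ca_set_umol_mol)
  a <- curve$a_umol_m2_s[ord]
  ca <- curve$ca_set_umol_mol[ord]
  if (length(a) <= window + k) return(structure(curve, ca_cutoff = NA_real_))
  sm <- as.numeric(stats::filter(a, rep(1 / window, window), sides = 2))
  dec <- diff(sm) < 0
  dec[is.na(dec)] <- FALSE
  run <- 0
  onset <- NA_integer_
  for (i in seq_along(dec)) {
    run <- if (dec[i]) run + 1 else 0
    if (run >= k) { onset <- i - k + 1; break }
  }
  if (is.na(onset)) return(structure(curve, ca_cutoff = NA_real_))
  cutoff <- ca[onset]
  out <- curve[curve$ca_set_umol_mol <= cutoff, , drop = FALSE]
  structure(out, ca_cutoff = cutoff)
}

#' DREAM MCMC sampler
#'
#' Differential Evolution Adaptive Metropolis: multiple parallel chains in
#' which proposals jump along difference vectors of randomly selected chain
#' pairs, scaled by `gamma = 2.38 / sqrt(2 delta d')` (with `delta` sampled
#' pairs and `d'` the number of dimensions updated). At every fifth
#' generation the scaling factor is set to 1 to enable jumps between modes.
#' Each proposal updates only a randomly selected subset of dimensions (the
#' crossover), whose per-value selection probabilities are adapted during
#' burn-in from the normalised jump distances they achieve. Outlier chains
#' (mean log-posterior over the second half of history below
#' Q1 - 2 IQR) are reset to the state of a randomly chosen non-outlier
#' chain during burn-in. Proposals falling outside the prior box are
#' reflected back inside.
#'
#' @param log_post Function of a named parameter vector returning the log
#'   posterior density (up to a constant).
#' @param lower,upper Named bound vectors defining the support.
#' @param n_chains Number of parallel chains (>= 3; default 7).
#' @param n_iter Generations per chain.
#' @param seed Integer seed; the full trajectory is reproducible.
#' @param delta_max Maximum number of chain pairs per proposal.
#' @param b_jitter Relative jitter half-width on the jump factor.
#' @param b_star SD of the small additive proposal noise.
#' @param n_cr Number of crossover values (CR = 1/n_cr, ..., 1).
#' @param adapt_frac Fraction of `n_iter` during which crossover
#'   probabilities adapt and outlier chains may be reset.
#' @param init Optional `n_chains` x d matrix of starting states
#'   (default: uniform draws over the support).
#' @return A `chain_ensemble`: list with `samples` (array
#'   `n_iter` x `n_chains` x d), `log_post` (matrix), `accept_rate`,
#'   `p_cr`, `n_outlier_resets`, `par_names`.
#' @export
dream_sample <- function(log_post, lower, upper, n_chains = 7, n_iter = 3000,
                         seed = 1, delta_max = 3, b_jitter = 0.05,
                         b_star = 1e-6, n_cr = 3, adapt_frac = 0.5,
                         init = NULL) {
  stopifnot(n_chains >= 3, n_iter >= 10, all(lower < upper))
  set.seed(seed)
  d <- length(lower)
  nm <- names(lower)
  X <- if (is.null(init))
    matrix(stats::runif(n_chains * d, rep(lower, each = n_chains),
                        rep(upper, each = n_chains)), n_chains, d)
  else init
  colnames(X) <- nm
  lp <- apply(X, 1, function(x) log_post(stats::setNames(x, nm)))
  samples <- array(NA_real_, c(n_iter, n_chains, d),
                   dimnames = list(NULL, NULL, nm))
  lp_hist <- matrix(NA_real_, n_iter, n_chains)
  cr_vals <- seq_len(n_cr) / n_cr
  p_cr <- rep(1 / n_cr, n_cr)
  jump_m <- rep(0, n_cr)   # accumulated squared normalised jump distance
  used_m <- rep(0, n_cr)
  n_accept <- 0
  n_prop <- 0
  n_resets <- 0
  adapt_until <- floor(adapt_frac * n_iter)
  rng <- upper - lower
  for (t in seq_len(n_iter)) {
    gamma_unit <- (t %% 5) == 0
    for (i in seq_len(n_chains)) {
      m <- sample.int(n_cr, 1, prob = p_cr)
      mask <- stats::runif(d) < cr_vals[m]
      if (!any(mask)) mask[sample.int(d, 1)] <- TRUE
      dprime <- sum(mask)
      delta <- sample.int(min(delta_max, (n_chains - 1L) %/% 2L), 1)
      others <- setdiff(seq_len(n_chains), i)
      pick <- sample(others, 2 * delta)
      r1 <- pick[seq_len(delta)]
      r2 <- pick[delta + seq_len(delta)]
      diffv <- colSums(X[r1, , drop = FALSE]) - colSums(X[r2, , drop = FALSE])
      g <- if (gamma_unit) 1 else 2.38 / sqrt(2 * delta * dprime)
      e <- stats::runif(d, -b_jitter, b_jitter)
      eps <- stats::rnorm(d, 0, b_star)
      xp <- X[i, ]
      step <- (1 + e) * g * diffv + eps
      xp[mask] <- xp[mask] + step[mask]
      # reflect into the support, then clamp any overshoot
      below <- xp < lower; xp[below] <- 2 * lower[below] - xp[below]
      above <- xp > upper; xp[above] <- 2 * upper[above] - xp[above]
      xp <- pmin(pmax(xp, lower), upper)
      lpp <- log_post(stats::setNames(xp, nm))
      n_prop <- n_prop + 1
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp[i]) {
        if (t <= adapt_until) {
          jump_m[m] <- jump_m[m] + sum(((xp - X[i, ]) / rng)^2)
        }
        X[i, ] <- xp
        lp[i] <- lpp
        n_accept <- n_accept + 1
      }
      if (t <= adapt_until) used_m[m] <- used_m[m] + 1
    }
    samples[t, , ] <- X
    lp_hist[t, ] <- lp
    if (t <= adapt_until && t %% 10 == 0 && all(used_m > 0)) {
      w <- jump_m / used_m
      if (sum(w) > 0) p_cr <- pmax(w / sum(w), 0.05 / n_cr)
      p_cr <- p_cr / sum(p_cr)
    }
    if (t <= adapt_until && t %% 20 == 0 && t >= 40) {
      half <- lp_hist[seq(floor(t / 2), t), , drop = FALSE]
      mlp <- colMeans(half)
      q <- stats::quantile(mlp, c(0.25, 0.75), names = FALSE)
      bad <- which(mlp < q[1] - 2 * (q[2] - q[1]))
      for (b in bad) {
        good <- sample(setdiff(seq_len(n_chains), bad), 1)
        X[b, ] <- X[good, ]
        lp[b] <- lp[good]
        n_resets <- n_resets + 1
      }
    }
  }
  if (n_accept == 0)
    warning("no proposals accepted: chains are stuck")
  structure(list(samples = samples, log_post = lp_hist,
                 accept_rate = n_accept / n_prop, p_cr = p_cr,
                 n_outlier_resets = n_resets, par_names = nm),
            class = "chain_ensemble")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' R-hat from between- and within-chain variances of a multi-chain sample.
#' Values near 1 indicate that the chains are sampling the same
#' distribution.
#'
#' @param x Either an iterations-by-chains matrix, or a `chain_ensemble`
#'   from [dream_sample()] together with `param`.
#' @param param Parameter name or index (for a `chain_ensemble`).
#' @param discard_frac Fraction of early iterations to discard first.
#' @return R-hat (scalar).
#' @export
gelman_rubin <- function(x, param = NULL, discard_frac = 0) {
  if (inherits(x, "chain_ensemble")) {
    stopifnot(!is.null(param))
    x <- x$samples[, , param]
  }
  x <- as.matrix(x)
  if (discard_frac > 0)
    x <- x[-seq_len(floor(discard_frac * nrow(x))), , drop = FALSE]
  n <- nrow(x); m <- ncol(x)
  stopifnot(m >= 2, n >= 10)
  means <- colMeans(x)
  w <- mean(apply(x, 2, stats::var))
  if (w == 0) {
    if (stats::var(means) == 0) return(1)
    stop("degenerate within-chain variance")
  }
  b_over_n <- stats::var(means)
  # values below 1 are finite-sample artifacts; floor so identical chains
  # report exactly 1
  sqrt(max(1, (n - 1) / n + b_over_n / w))
}

#' Settings for the A-Ci fitting pipeline
#'
#' Defaults mirror the full-scale estimation protocol (7 chains, 80000
#' iterations, discard to convergence, thin to 1 percent); smaller budgets
#' for testing are set through the same fields.
#'
#' @param n_chains,n_iter Chains and generations for [dream_sample()].
#' @param burn_frac Fraction of iterations discarded as pre-convergence.
#' @param thin_frac Fraction of post-burn samples retained.
#' @param rhat_threshold Convergence threshold on R-hat (1.1).
#' @param max_restarts If not converged, rerun once with doubled
#'   iterations.
#' @param seed Integer seed.
#' @return List of settings.
#' @export
aci_fit_settings <- function(n_chains = 7, n_iter = 80000, burn_frac = 0.5,
                             thin_frac = 0.01, rhat_threshold = 1.1,
                             max_restarts = 1, seed = 1) {
  list(n_chains = n_chains, n_iter = n_iter, burn_frac = burn_frac,
       thin_frac = thin_frac, rhat_threshold = rhat_threshold,
       max_restarts = max_restarts, seed = seed)
}

#' Fit an A-Ci curve by DREAM MCMC
#'
#' Full estimation pipeline: truncate the TPU-affected high-CO2 region,
#' sample the posterior of (`vcmax25`, `jmax25`, `theta_cj`, `sigma`) with
#' [dream_sample()], discard pre-convergence samples, check Gelman-Rubin
#' R-hat, thin, and summarise. The fitted model is the two-limitation
#' (carboxylation, RuBP regeneration) family with quadratic smoothing;
#' predictions are made at each record's measured Ci.
#'
#' @param curve An `aci_curve` with at least 20 usable records.
#' @param priors An [aci_priors()].
#' @param settings An [aci_fit_settings()].
#' @param fixed A [photo_params()] for the non-sampled constants.
#' @return An `aci_fit` list: `summary` (data.frame mean/sd/q2.5/q50/q97.5
#'   per parameter; `NULL` if not converged), `converged`, `rhat`,
#'   `samples` (thinned posterior draws), `ensemble`, `ca_cutoff`,
#'   `n_records`.
#' @export
fit_aci <- function(curve, priors = aci_priors(),
                    settings = aci_fit_settings(),
                    fixed = photo_params()) {
  curve <- truncate_tpu_region(curve)
  if ("solver_ok" %in% names(curve))
    curve <- curve[curve$solver_ok %in% c(TRUE, NA), , drop = FALSE]
  if (nrow(curve) < 20) stop("need at least 20 usable records")
  lp <- function(theta) {
    if (any(theta < priors$lower) || any(theta > priors$upper)) return(-Inf)
    aci_loglik(theta, curve, fixed)
  }
  n_iter <- settings$n_iter
  seed <- settings$seed
  for (attempt in 0:settings$max_restarts) {
    ens <- dream_sample(lp, priors$lower, priors$upper,
                        n_chains = settings$n_chains, n_iter = n_iter,
                        seed = seed + attempt)
    burn <- floor(settings$burn_frac * n_iter)
    post <- ens$samples[(burn + 1):n_iter, , , drop = FALSE]
    rhat <- vapply(ens$par_names, function(p)
      gelman_rubin(post[, , p]), numeric(1))
    converged <- all(rhat < settings$rhat_threshold)
    if (converged) break
    n_iter <- 2 * n_iter
  }
  step <- max(1L, round(1 / settings$thin_frac))
  keep <- seq(1, dim(post)[1], by = step)
  thin <- do.call(rbind, lapply(seq_len(dim(post)[2]), function(ch)
    post[keep, ch, , drop = TRUE]))
  colnames(thin) <- ens$par_names
  thin <- as.data.frame(thin)
  summary_df <- if (converged) {
    data.frame(
      parameter = ens$par_names,
      mean = vapply(thin, mean, numeric(1)),
      sd = vapply(thin, stats::sd, numeric(1)),
      q2.5 = vapply(thin, stats::quantile, numeric(1), probs = 0.025,
                    names = FALSE),
      q50 = vapply(thin, stats::quantile, numeric(1), probs = 0.5,
                   names = FALSE),
      q97.5 = vapply(thin, stats::quantile, numeric(1), probs = 0.975,
                     names = FALSE),
      row.names = NULL)
  } else NULL
  structure(list(summary = summary_df, converged = converged, rhat = rhat,
                 samples = thin, ensemble = ens,
                 ca_cutoff = attr(curve, "ca_cutoff"),
                 n_records = nrow(curve)),
            class = "aci_fit")
}
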