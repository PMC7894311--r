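#' Stomatal parameters for the Medlyn unified model
#'
#' @param g0 Residual conductance (mol m-2 s-1).
#' @param g1 Slope parameter (kPa^0.5-scaled, dimensionless in the Medlyn
#'   form); 4.3 is the global C3 mean.
#' @return A `stomatal_params` list.
#' @export
stomatal_params <- function(g0 = 0.01, g1 = 4.3) {
  stopifnot(g0 >= 0, g1 > 0)
  structure(list(g0 = g0, g1 = g1), class = "stomatal_params")
}

#' Medlyn unified stomatal conductance
#'
#' `gs = g0 + 1.6 (1 + g1/sqrt(D)) max(A, 0) / Ca`, in mol H2O m-2 s-1.
#' Negative assimilation is floored at zero inside the model so conductance
#' never drops below `g0`.
#'
#' @param a_net Net assimilation (umol CO2 m-2 s-1).
#' @param ca Atmospheric CO2 (umol/mol).
#' @param vpd Vapour pressure deficit (kPa), strictly positive.
#' @param stomatal A [stomatal_params()].
#' @return Stomatal conductance (mol m-2 s-1).
#' @export
medlyn_gs <- function(a_net, ca, vpd, stomatal = stomatal_params()) {
  if (any(ca <= 0)) stop("ca must be > 0")
  if (any(vpd <= 0)) stop("vpd must be > 0")
  stomatal$g0 + 1.6 * (1 + stomatal$g1 / sqrt(vpd)) * pmax(a_net, 0) / ca
}

# ---- vectorised demand kernel -------------------------------------------
#
# The sensitivity analyses evaluate millions of model runs, so the demand
# side is precomputed once per (parameter matrix, model, irradiance) and the
# Ci-dependent part kept to a handful of vector operations inside the
# bisection loop. `par` is a list of parameter vectors (the 14 fields of
# photo_params, each length n or 1).

demand_precompute <- function(par, config, irradiance, oi = 21) {
  alpha_i <- 0.5 * (1 - par$f_loss)
  aai <- par$absorptance_a * alpha_i * irradiance
  jmax <- par$a_jv + par$b_jv * par$vcmax25
  j <- switch(config$etrans_hypothesis,
    linear_cbgb = aai,
    hyperbola_harley = aai / sqrt(1 + (aai / jmax)^2),
    nonrect_fw = smaller_root(par$theta_j, aai, jmax))
  gstar <- par$ko_kc_ratio * par$kc_half * oi / (2 * par$ko_half)
  pre <- list(
    vcmax = par$vcmax25,
    km = par$kc_half * (1 + oi / par$ko_half),
    j4 = j / 4,
    gstar = gstar,
    gstar2 = 2 * gstar,
    rd = par$b_rv * par$vcmax25,
    smoothing = config$selection == "quadratic_smoothing",
    tpu = config$tpu_included,
    theta_cj = par$theta_cj,
    theta_cjp = par$theta_cjp)
  if (config$tpu_included) {
    pre$tpu3 <- 3 * par$b_tv * par$vcmax25
    pre$tpu_thresh <- (1 + 3 * par$alpha_tpu) * gstar
  }
  pre
}

# net assimilation at Ci (Pa) from a precomputed kernel; pure vector ops
demand_a <- function(pre, ci) {
  ac <- pre$vcmax * ci / (ci + pre$km)
  aj <- pre$j4 * ci / (ci + pre$gstar2)
  if (pre$smoothing) {
    ag <- smaller_root_fast(pre$theta_cj, ac, aj)
    if (pre$tpu) {
      denom <- ci - pre$tpu_thresh
      ok <- denom > 0
      if (any(ok)) {
        ap <- pre$tpu3 * ci / denom
        ag2 <- smaller_root_fast(pre$theta_cjp, ag, ap)
        ag[ok] <- ag2[ok]
      }
    }
  } else {
    ag <- pmin(ac, aj)
    if (pre$tpu) {
      denom <- ci - pre$tpu_thresh
      ok <- denom > 0
      if (any(ok)) {
        ap <- pre$tpu3 * ci / denom
        ag[ok] <- pmin(ag, ap)[ok]
      }
    }
  }
  ag * (1 - pre$gstar / ci) - pre$rd
}

# smaller_root without the domain check (theta validated upstream)
smaller_root_fast <- function(theta, x1, x2) {
  s <- x1 + x2
  disc <- s * s - 4 * theta * x1 * x2
  disc[disc < 0] <- 0
  2 * x1 * x2 / (s + sqrt(disc))
}

#' Vectorised coupled Ci solve
#'
#' Solves the supply/demand balance `Ci = Ca - 1.6 A / gs` (mole-fraction
#' form) jointly with the demand model for many parameter draws at once, by
#' safeguarded bisection on the supply-minus-demand residual. Bisection is
#' used deliberately: minimum-rule selection makes the demand curve
#' non-smooth at rate transitions, which breaks derivative-based solvers.
#'
#' @param par List of parameter vectors (fields of [photo_params()], each
#'   length n or 1).
#' @param config A [model_config()].
#' @param ca Atmospheric CO2 (umol/mol, scalar).
#' @param irradiance Incident light (umol m-2 s-1, scalar).
#' @param stomatal A [stomatal_params()].
#' @param vpd,pressure,oi Environment scalars (kPa).
#' @param iters Number of bisection iterations; 50 halvings of the initial
#'   bracket reduce it by ~1e15, far below measurement relevance.
#' @return Vector of net assimilation rates, with attribute `"ci_pa"`.
#' @export
solve_ci_vec <- function(par, config, ca, irradiance,
                         stomatal = stomatal_params(), vpd = 1,
                         pressure = 101.325, oi = 21, iters = 50) {
  pre <- demand_precompute(par, config, irradiance, oi)
  n <- length(pre$vcmax)
  to_pa <- pressure * 1e-3
  gfac <- 1.6 * (1 + stomatal$g1 / sqrt(vpd)) / ca
  # supply residual in Pa; at Ci -> 0 demand A < 0 so supply > Ci (positive
  # residual); the upper end covers the A <= 0 solution Ci = Ca + 1.6 Rd/g0
  resid <- function(ci_pa) {
    a <- demand_a(pre, ci_pa)
    gs <- stomatal$g0 + gfac * pmax(a, 0)
    (ca - 1.6 * a / gs) * to_pa - ci_pa
  }
  lo <- rep(1e-4, n)
  hi <- rep((ca + 1.6 * max(pre$rd) / stomatal$g0 + 1) * to_pa, n)
  for (k in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    up <- resid(mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  ci <- 0.5 * (lo + hi)
  a <- demand_a(pre, ci)
  attr(a, "ci_pa") <- ci
  a
}

#' Solve the coupled assimilation-conductance-Ci system
#'
#' Single-leaf steady state where the demand model (at Ci), the Medlyn
#' conductance (at A) and the diffusive supply `Ci = Ca - 1.6 A / gs`
#' are simultaneously satisfied. Uses safeguarded bisection on the Ci
#' residual (robust to the derivative discontinuities of minimum-rule
#' selection) to |residual| < 1e-8 Ca.
#'
#' @param env A [leaf_env()].
#' @param params A [photo_params()].
#' @param config A [model_config()].
#' @param stomatal A [stomatal_params()].
#' @return A `photo_result` (see [assimilation_at_ci()]) with `ci` (Pa) and
#'   `gs` (mol m-2 s-1) filled in, plus fields `converged` and `residual_pa`.
#' @export
solve_coupled <- function(env = leaf_env(), params = photo_params(),
                          config = model_config("M1111"),
                          stomatal = stomatal_params()) {
  par <- params[c("vcmax25", "kc_half", "ko_half", "ko_kc_ratio",
                  "absorptance_a", "f_loss", "theta_j", "a_jv", "b_jv",
                  "b_tv", "alpha_tpu", "b_rv", "theta_cj", "theta_cjp")]
  # honour direct jmax25/rd overrides by folding them into the scaling form
  dep <- derive_dependent(params)
  par$a_jv <- dep$jmax25 - par$b_jv * par$vcmax25
  par$b_rv <- dep$rd / par$vcmax25
  par$b_tv <- dep$tpu25 / par$vcmax25
  a <- solve_ci_vec(par, config, env$ca, env$irradiance, stomatal,
                    vpd = env$vpd, pressure = env$pressure, oi = env$oi,
                    iters = 64)
  ci <- attr(a, "ci_pa")
  res <- assimilation_at_ci(ci, env, params, config)
  res$gs <- medlyn_gs(res$a_net, env$ca, env$vpd, stomatal)
  supply <- (env$ca - 1.6 * res$a_net / res$gs) * env$pressure * 1e-3
  res$residual_pa <- supply - ci
  res$converged <- abs(res$residual_pa) <
    1e-8 * co2_to_pa(env$ca, env$pressure) + 1e-10
  res
}

#' CO2 and light response curves
#'
#' Evaluates the coupled model over a grid of atmospheric CO2 or incident
#' light, returning the realised rate together with the potential-rate
#' decomposition. Default grids: Ca from 50 to 1500 umol/mol in steps of 50
#' at I = 960 umol m-2 s-1, and I from 10 to 1960 umol m-2 s-1 in steps of
#' 50 at Ca = 400 umol/mol.
#'
#' @param params A [photo_params()].
#' @param config A [model_config()].
#' @param stomatal A [stomatal_params()].
#' @param axis `"ca"` or `"irradiance"`.
#' @param grid Grid of the chosen axis variable; `NULL` for the default.
#' @param env Baseline [leaf_env()] supplying the non-varying conditions.
#' @return A data.frame with columns `model_id`, `ca_umol_mol`,
#'   `i_umol_m2_s`, `ci_pa`, `a_net`, `ac_g`, `aj_g`, `ap_g`, `acj_g`, `j`,
#'   `gs`, `limiting_state`.
#' @export
response_curve <- function(params = photo_params(),
                           config = model_config("M1111"),
                           stomatal = stomatal_params(),
                           axis = c("ca", "irradiance"), grid = NULL,
                           env = leaf_env()) {
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "ca") seq(50, 1500, by = 50) else seq(10, 1960, by = 50)
  if (!length(grid)) stop("empty grid")
  if (axis == "ca") env$irradiance <- 960 else env$ca <- 400
  rows <- lapply(grid, function(g) {
    e <- env
    e[[if (axis == "ca") "ca" else "irradiance"]] <- g
    r <- solve_coupled(e, params, config, stomatal)
    data.frame(model_id = config$model_id, ca_umol_mol = e$ca,
               i_umol_m2_s = e$irradiance, ci_pa = r$ci, a_net = r$a_net,
               ac_g = r$ac_g, aj_g = r$aj_g, ap_g = r$ap_g,
               acj_g = r$acj_g, j = r$j, gs = r$gs,
               limiting_state = r$limiting_state,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
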