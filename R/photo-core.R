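#' Photorespiratory CO2 compensation point
#'
#' Gamma-star from the RuBisCO turnover-number ratio and the
#' Michaelis-Menten constants: `(ko:kc) * Kc * Oi / (2 * Ko)`. With `Kc` in
#' Pa and `Oi`, `Ko` in kPa the kPa units cancel and the result is in Pa.
#'
#' @param params A [photo_params()] object (or list with the same fields).
#' @param env A [leaf_env()] object.
#' @return Gamma-star (Pa).
#' @export
gamma_star <- function(params, env = leaf_env()) {
  if (any(params$ko_half <= 0)) stop("ko_half must be > 0")
  params$ko_kc_ratio * params$kc_half * env$oi / (2 * params$ko_half)
}

#' RuBisCO-limited gross carboxylation rate
#'
#' Michaelis-Menten in Ci with competitive inhibition by O2:
#' `Vcmax * Ci / (Ci + Kc * (1 + Oi/Ko))`.
#'
#' @param ci Intercellular CO2 partial pressure (Pa).
#' @inheritParams gamma_star
#' @return Gross rate (umol CO2 m-2 s-1), saturating at `Vcmax`.
#' @export
ac_gross <- function(ci, params, env = leaf_env()) {
  if (any(ci < 0)) stop("ci must be >= 0")
  km <- params$kc_half * (1 + env$oi / params$ko_half)
  params$vcmax25 * ci / (ci + km)
}

#' Electron transport rate
#'
#' Three alternative light responses of the electron transport rate `J`.
#' All share the apparent quantum efficiency `a * alpha_i` with
#' `alpha_i = 0.5 * (1 - f_loss)`:
#' \itemize{
#'   \item `nonrect_fw`: smaller root of the non-rectangular hyperbola
#'     `theta_j J^2 - (a alpha_i I + Jmax) J + a alpha_i I Jmax = 0`;
#'   \item `hyperbola_harley`: `a alpha_i I / sqrt(1 + (a alpha_i I / Jmax)^2)`;
#'   \item `linear_cbgb`: `a alpha_i I`, unbounded in light.
#' }
#'
#' @param irradiance Incident light (umol photons m-2 s-1).
#' @param params A [photo_params()] object.
#' @param hypothesis One of the three forms above.
#' @return `J` (umol e m-2 s-1).
#' @export
electron_transport <- function(irradiance, params,
                               hypothesis = c("nonrect_fw",
                                              "hyperbola_harley",
                                              "linear_cbgb")) {
  hypothesis <- match.arg(hypothesis)
  if (any(irradiance < 0)) stop("irradiance must be >= 0")
  alpha_i <- 0.5 * (1 - params$f_loss)
  aai <- params$absorptance_a * alpha_i * irradiance
  if (hypothesis == "linear_cbgb") return(aai)
  jmax <- derive_dependent(params)$jmax25
  if (any(jmax <= 0)) stop("jmax25 must be > 0 for saturating forms")
  switch(hypothesis,
    hyperbola_harley = aai / sqrt(1 + (aai / jmax)^2),
    nonrect_fw = smaller_root(params$theta_j, aai, jmax))
}

#' RuBP-regeneration-limited gross rate
#'
#' `Aj,g = (J/4) * Ci / (Ci + 2 Gamma-star)`: four electrons per
#' carboxylation, with the photorespiratory drawdown in the denominator.
#'
#' @param ci Intercellular CO2 (Pa).
#' @param j Electron transport rate (umol e m-2 s-1).
#' @param gamma_star Compensation point (Pa).
#' @return Gross rate (umol CO2 m-2 s-1).
#' @export
aj_gross <- function(ci, j, gamma_star) {
  if (any(ci < 0)) stop("ci must be >= 0")
  (j / 4) * ci / (ci + 2 * gamma_star)
}

#' TPU-limited gross rate
#'
#' `Ap,g = 3 TPU Ci / (Ci - (1 + 3 alpha_tpu) Gamma-star)`, where
#' `alpha_tpu` is the fraction of glycolate carbon exported and not
#' returned to the chloroplast. The minus sign in the denominator is
#' required for internal consistency: with `alpha_tpu = 0`, multiplying by
#' the photorespiration factor `(1 - Gamma-star/Ci)` of the net
#' assimilation equation yields exactly `3 TPU`. Below the validity
#' boundary `Ci <= (1 + 3 alpha_tpu) Gamma-star` the rate is not a
#' meaningful limitation and `Inf` is returned so that it never wins the
#' limiting-rate selection.
#'
#' @param ci Intercellular CO2 (Pa).
#' @param tpu TPU capacity (umol CO2 m-2 s-1).
#' @param alpha_tpu Non-returned glycolate fraction (0-1).
#' @param gamma_star Compensation point (Pa).
#' @return Gross rate (umol CO2 m-2 s-1); `Inf` where not applicable.
#' @export
ap_gross <- function(ci, tpu, alpha_tpu, gamma_star) {
  denom <- ci - (1 + 3 * alpha_tpu) * gamma_star
  out <- 3 * tpu * ci / denom
  out[denom <= 0] <- Inf
  out
}

#' Smaller root of the co-limitation quadratic
#'
#' Solves `theta z^2 - (x1 + x2) z + x1 x2 = 0` for its smaller root, the
#' non-rectangular-hyperbola smoothing of two potentially limiting rates.
#' At `theta = 1` the quadratic factorises and the root is `min(x1, x2)`;
#' at `theta = 0` the expression degenerates to the rectangular hyperbola
#' `x1 x2 / (x1 + x2)`. The root is computed in the multiply-by-conjugate
#' form `2 x1 x2 / (x1 + x2 + sqrt((x1 + x2)^2 - 4 theta x1 x2))`, which
#' is exact at `theta = 0` and avoids cancellation as `theta -> 0`.
#'
#' @param theta Curvature parameter in `[0, 1]` (1 = no smoothing).
#' @param x1,x2 Non-negative rates.
#' @return The smaller root; always `<= min(x1, x2)`.
#' @export
smaller_root <- function(theta, x1, x2) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  s <- x1 + x2
  disc <- s * s - 4 * theta * x1 * x2
  disc[disc < 0] <- 0  # roundoff guard at exact co-limitation, theta = 1
  2 * x1 * x2 / (s + sqrt(disc))
}

#' Select or smooth the limiting rates
#'
#' Combines the potentially limiting gross rates into a single gross
#' assimilation rate. Under `minimum` selection the smallest of the present
#' rates is taken. Under `quadratic_smoothing` the rates are combined in
#' two stages: first `Ac,g` with `Aj,g` using `theta_cj` (yielding the
#' latent `Acj,g`), then the result with `Ap,g` using `theta_cjp`. When TPU
#' is excluded (or inapplicable at this Ci) only the first stage applies.
#'
#' @param ac_g,aj_g Carboxylation- and RuBP-regeneration-limited gross
#'   rates (umol CO2 m-2 s-1).
#' @param ap_g TPU-limited gross rate, or `NULL`/`Inf` when absent.
#' @param config A [model_config()].
#' @param params A [photo_params()] (supplies `theta_cj`, `theta_cjp`).
#' @return List with `a_gross`, the latent `acj_g` (equal to `a_gross` for
#'   minimum selection), and `limiting_state` (`"Ac"`, `"Aj"` or `"Ap"`,
#'   the smallest potential rate).
#' @export
select_rate <- function(ac_g, aj_g, ap_g = NULL, config, params) {
  if (is.null(ap_g)) ap_g <- rep(Inf, length(ac_g))
  state <- c("Ac", "Aj", "Ap")[max.col(-cbind(ac_g, aj_g, ap_g),
                                       ties.method = "first")]
  if (config$selection == "minimum") {
    ag <- pmin(ac_g, aj_g, ap_g)
    acj <- pmin(ac_g, aj_g)
  } else {
    acj <- smaller_root(params$theta_cj, ac_g, aj_g)
    ag <- ifelse(is.finite(ap_g),
                 smaller_root(params$theta_cjp, acj, ap_g), acj)
  }
  list(a_gross = ag, acj_g = acj, limiting_state = state)
}

#' Net assimilation from the gross rate
#'
#' `A = Ag (1 - Gamma-star/Ci) - Rd`: the first factor scales gross
#' carboxylation for photorespiratory CO2 release (so `A = -Rd` exactly at
#' `Ci = Gamma-star`), and dark respiration is subtracted.
#'
#' @param a_gross Gross assimilation (umol CO2 m-2 s-1).
#' @param ci Intercellular CO2 (Pa), strictly positive.
#' @param gamma_star Compensation point (Pa).
#' @param rd Dark respiration (umol CO2 m-2 s-1).
#' @return Net assimilation (umol CO2 m-2 s-1).
#' @export
net_assimilation <- function(a_gross, ci, gamma_star, rd) {
  if (any(ci <= 0)) stop("ci must be > 0")
  a_gross * (1 - gamma_star / ci) - rd
}

#' Evaluate a model at prescribed Ci
#'
#' The full demand-side evaluation chain at a given intercellular CO2:
#' compensation point, derived capacities, electron transport, the two or
#' three potentially limiting rates, limiting-rate selection/smoothing and
#' net assimilation. Stomata are not involved; see [solve_coupled()] for
#' the supply-coupled evaluation.
#'
#' @param ci Intercellular CO2 partial pressure (Pa), strictly positive.
#' @param env A [leaf_env()] (supplies irradiance and Oi).
#' @param params A [photo_params()].
#' @param config A [model_config()].
#' @return A `photo_result` list: `a_net`, `a_gross`, `ac_g`, `aj_g`,
#'   `ap_g` (`NA` when TPU excluded), `acj_g`, `j`, `ci`, `gamma_star`,
#'   `rd`, `limiting_state`. `gs` is `NA` here (no stomatal coupling).
#' @export
assimilation_at_ci <- function(ci, env = leaf_env(), params = photo_params(),
                               config = model_config("M1111")) {
  gs_pa <- gamma_star(params, env)
  dep <- derive_dependent(params)
  j <- electron_transport(env$irradiance, params, config$etrans_hypothesis)
  ac <- ac_gross(ci, params, env)
  aj <- aj_gross(ci, j, gs_pa)
  ap <- if (config$tpu_included)
    ap_gross(ci, dep$tpu25, params$alpha_tpu, gs_pa) else NULL
  sel <- select_rate(ac, aj, ap, config, params)
  a <- net_assimilation(sel$a_gross, ci, gs_pa, dep$rd)
  structure(list(
    a_net = a, a_gross = sel$a_gross, ac_g = ac, aj_g = aj,
    ap_g = if (is.null(ap)) NA_real_ else ap, acj_g = sel$acj_g,
    j = j, ci = ci, gs = NA_real_, gamma_star = gs_pa, rd = dep$rd,
    limiting_state = sel$limiting_state), class = "photo_result")
}
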