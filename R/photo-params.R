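#' Photosynthesis parameter set
#'
#' Builds the full kinetic parameter set used by every model in the ensemble.
#' All values are 25 degC reference values; no temperature response functions
#' are applied anywhere in the package. Derived capacities (`J_max,25`,
#' `TPU_25`, `R_d`) are computed from `vcmax25` through the linear scaling
#' relationships `jmax25 = a_jv + b_jv * vcmax25`, `tpu25 = b_tv * vcmax25`
#' and `rd = b_rv * vcmax25`, unless overridden (the historical FvCB
#' parameterisation quotes `J_max` and `R_d` directly).
#'
#' @param preset One of `"central"` (midpoints of the sensitivity-analysis
#'   ranges, the ensemble default), `"fvcb_original"` or `"cbgb_original"`
#'   (the two historical parameterisations unified to common units).
#' @param ... Named overrides of individual fields (e.g. `vcmax25 = 98`).
#' @param jmax25,rd Optional direct overrides of the derived capacities; when
#'   `NULL` (default) they are computed from the scaling relationships.
#'
#' @return An object of class `photo_params`: a named list with fields
#'   `vcmax25` (umol CO2 m-2 s-1), `kc_half` (Pa), `ko_half` (kPa),
#'   `ko_kc_ratio` (-), `absorptance_a` (-), `f_loss` (-), `theta_j` (-),
#'   `a_jv` (umol e m-2 s-1), `b_jv` (e CO2-1), `b_tv` (-), `alpha_tpu` (-),
#'   `b_rv` (-), `theta_cj` (-), `theta_cjp` (-), plus the optional
#'   `jmax25`/`rd` overrides.
#'
#' @details The intrinsic quantum efficiency of electron transport is always
#'   derived as `alpha_i = 0.5 * (1 - f_loss)` (two photons per electron for
#'   full linear transport) and never stored.
#' @export
photo_params <- function(preset = c("central", "fvcb_original", "cbgb_original"),
                         ..., jmax25 = NULL, rd = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    central = list(
      vcmax25 = 50, kc_half = 40.45, ko_half = 27.85, ko_kc_ratio = 0.21,
      absorptance_a = 0.80, f_loss = 0.23, theta_j = 0.90,
      a_jv = 29.1, b_jv = 1.6355, b_tv = 0.167, alpha_tpu = 0.50,
      b_rv = 0.015, theta_cj = 0.90, theta_cjp = 0.90),
    fvcb_original = list(
      vcmax25 = 98, kc_half = 46, ko_half = 33, ko_kc_ratio = 0.21,
      absorptance_a = 0.80, f_loss = 0.23, theta_j = 0.67,
      a_jv = 29.1, b_jv = 1.6355, b_tv = 0.167, alpha_tpu = 0,
      b_rv = 0.015, theta_cj = 1, theta_cjp = 1),
    cbgb_original = list(
      vcmax25 = 200, kc_half = 30, ko_half = 30, ko_kc_ratio = 0.38,
      absorptance_a = 0.86, f_loss = 0.52, theta_j = 0.90,
      a_jv = 29.1, b_jv = 1.6355, b_tv = 0.167, alpha_tpu = 0,
      b_rv = 0.015, theta_cj = 0.95, theta_cjp = 0.98))
  # historical presets quote some capacities directly rather than via scaling
  if (preset == "fvcb_original") {
    if (is.null(jmax25)) jmax25 <- 210
    if (is.null(rd)) rd <- 1.1
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p$jmax25 <- jmax25
  p$rd <- rd
  validate_photo_params(p)
  structure(p, class = "photo_params")
}

validate_photo_params <- function(p) {
  rates <- c("vcmax25", "kc_half", "ko_half", "ko_kc_ratio", "a_jv", "b_jv",
             "b_tv", "b_rv")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || any(p[[nm]] <= 0))
      stop(nm, " must be > 0")
  for (nm in c("theta_j", "theta_cj", "theta_cjp"))
    if (any(p[[nm]] <= 0) || any(p[[nm]] > 1))
      stop(nm, " must lie in (0, 1]")
  for (nm in c("absorptance_a", "f_loss"))
    if (any(p[[nm]] < 0) || any(p[[nm]] >= 1))
      stop(nm, " must lie in [0, 1)")
  if (any(p$alpha_tpu < 0) || any(p$alpha_tpu > 1))
    stop("alpha_tpu must lie in [0, 1]")
  invisible(p)
}

#' Derived capacity parameters
#'
#' Computes the dependent capacities from `vcmax25`: the maximum electron
#' transport rate via the linear `J_max`-to-`V_cmax` regression, the TPU
#' capacity, and dark respiration. Direct overrides stored on the parameter
#' object (historical presets) take precedence.
#'
#' @param params A [photo_params()] object.
#' @return Named list with `jmax25` (umol e m-2 s-1), `tpu25` and `rd`
#'   (umol CO2 m-2 s-1).
#' @export
derive_dependent <- function(params) {
  stopifnot(all(params$vcmax25 > 0))
  jmax25 <- if (!is.null(params$jmax25)) params$jmax25 else
    params$a_jv + params$b_jv * params$vcmax25
  rd <- if (!is.null(params$rd)) params$rd else params$b_rv * params$vcmax25
  list(jmax25 = jmax25, tpu25 = params$b_tv * params$vcmax25, rd = rd)
}

#' Driving environment
#'
#' @param ca Atmospheric CO2 mole fraction (umol/mol).
#' @param irradiance Incident photosynthetically active radiation
#'   (umol photons m-2 s-1).
#' @param oi Internal O2 partial pressure (kPa); 21 kPa is standard
#'   atmospheric O2.
#' @param vpd Leaf-to-air vapour pressure deficit (kPa).
#' @param pressure Air pressure (kPa), used for the umol/mol to Pa
#'   conversion `Ca[Pa] = ca * pressure * 1e-3`.
#' @param leaf_temp Leaf temperature (degC). Only 25 degC is supported: all
#'   parameters are 25 degC reference values and no temperature scaling is
#'   implemented.
#' @return An `environment_leaf` list.
#' @export
leaf_env <- function(ca = 400, irradiance = 1000, oi = 21, vpd = 1,
                     pressure = 101.325, leaf_temp = 25) {
  stopifnot(ca >= 0, all(irradiance >= 0), oi >= 0, vpd >= 0, pressure > 0)
  structure(list(ca = ca, irradiance = irradiance, oi = oi, vpd = vpd,
                 pressure = pressure, leaf_temp = leaf_temp),
            class = "environment_leaf")
}

#' Convert a CO2 mole fraction to partial pressure
#' @param umol_mol CO2 mole fraction (umol/mol).
#' @param pressure Air pressure (kPa).
#' @return Partial pressure in Pa.
#' @export
co2_to_pa <- function(umol_mol, pressure = 101.325) umol_mol * pressure * 1e-3

#' @rdname co2_to_pa
#' @param pa CO2 partial pressure (Pa).
#' @export
co2_to_umol_mol <- function(pa, pressure = 101.325) pa / (pressure * 1e-3)

#' Sensitivity-analysis parameter ranges
#'
#' The 14 varied parameters with their central values and uniform
#' sensitivity-analysis ranges (nominally +/-10 percent of the central
#' value; the printed ranges are used where rounding differs).
#'
#' @return A data.frame with columns `name`, `low`, `central`, `high` and
#'   `process` (the process each parameter belongs to: carboxylation,
#'   electron_transport, tpu or limiting_rate_selection).
#' @export
param_ranges <- function() {
  df <- data.frame(
    name = c("vcmax25", "kc_half", "ko_half", "ko_kc_ratio", "b_rv",
             "absorptance_a", "f_loss", "theta_j", "a_jv", "b_jv",
             "b_tv", "alpha_tpu",
             "theta_cj", "theta_cjp"),
    low  = c(45, 36.4, 25.1, 0.19, 0.0135,
             0.72, 0.207, 0.81, 26.2, 1.467,
             0.15, 0.45,
             0.81, 0.81),
    central = c(50, 40.45, 27.85, 0.21, 0.015,
                0.80, 0.23, 0.90, 29.1, 1.6355,
                0.167, 0.50,
                0.90, 0.90),
    high = c(55, 44.5, 30.6, 0.23, 0.0165,
             0.88, 0.253, 0.99, 32.0, 1.804,
             0.183, 0.55,
             0.99, 0.99),
    process = c(rep("carboxylation", 5),
                rep("electron_transport", 5),
                rep("tpu", 2),
                rep("limiting_rate_selection", 2)),
    stringsAsFactors = FALSE)
  stopifnot(all(df$low < df$high), all(df$low <= df$central),
            all(df$central <= df$high))
  df
}

#' Process decomposition of the model
#'
#' The four processes of the process-level sensitivity analysis, each with
#' its alternative hypotheses and member parameters. The four member sets
#' partition all 14 varied parameters; dark respiration scaling (`b_rv`)
#' is grouped with carboxylation.
#'
#' @return Named list of process specs, each with `hypotheses` (character)
#'   and `member_params` (character).
#' @export
process_specs <- function() {
  rng <- param_ranges()
  members <- split(rng$name, rng$process)
  list(
    carboxylation = list(
      hypotheses = "michaelis_menten",
      member_params = members$carboxylation),
    electron_transport = list(
      hypotheses = c("nonrect_fw", "hyperbola_harley", "linear_cbgb"),
      member_params = members$electron_transport),
    tpu = list(
      hypotheses = c("absent", "present"),
      member_params = members$tpu),
    limiting_rate_selection = list(
      hypotheses = c("minimum", "quadratic_smoothing"),
      member_params = members$limiting_rate_selection))
}
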