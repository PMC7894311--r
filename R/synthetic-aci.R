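#' High-resolution A-Ci measurement Ca sequence
#'
#' The setpoint protocol of the high-resolution gas-exchange measurements:
#' a conventional descending leg from 400 to 50 umol/mol, a return to a
#' conservative estimate of the start of the co-limitation transition zone
#' (305 umol/mol) followed by a fine scan in 5 umol/mol increments up to
#' 1000 umol/mol, then a few larger steps to capture the top of a standard
#' A-Ci curve.
#'
#' @param descending Setpoints of the descending leg (umol/mol).
#' @param scan_from,scan_to,scan_by Fine-scan bounds and increment.
#' @param high_extension Setpoints above the scan.
#' @return Data.frame with columns `ca` (umol/mol) and `phase`
#'   (`descending`, `transition_scan`, `high_extension`).
#' @export
protocol_ca_sequence <- function(descending = c(400, 300, 200, 150, 100, 75, 50),
                                 scan_from = 305, scan_to = 1000, scan_by = 5,
                                 high_extension = c(1100, 1250, 1500, 1800)) {
  scan <- seq(scan_from, scan_to, by = scan_by)
  data.frame(
    ca = c(descending, scan, high_extension),
    phase = c(rep("descending", length(descending)),
              rep("transition_scan", length(scan)),
              rep("high_extension", length(high_extension))),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic high-resolution A-Ci curve
#'
#' Drives the coupled leaf model over the measurement protocol and adds
#' iid Gaussian noise to the net assimilation rate, reproducing the
#' statistical structure assumed by the curve-fitting likelihood (the
#' instrument reports Ci, so the noise-free Ci of the coupled solve is
#' recorded alongside the noisy A).
#'
#' @param true_params A [photo_params()] holding the known truth.
#' @param config A [model_config()]; the default smooths the two-rate
#'   transition with the parameter set's `theta_cj`.
#' @param stomatal A [stomatal_params()].
#' @param noise_sd Gaussian measurement noise on A (umol CO2 m-2 s-1);
#'   0.3 is typical closed-chamber instrument noise.
#' @param seed Integer seed.
#' @param env Baseline [leaf_env()]; irradiance defaults to the saturating
#'   2000 umol m-2 s-1 used during the measurements.
#' @param ca_sequence Setpoint table from [protocol_ca_sequence()].
#' @return An `aci_curve`: data.frame with columns `obs`, `phase`,
#'   `ca_set_umol_mol`, `ci_pa`, `ci_umol_mol`, `a_umol_m2_s` (observed),
#'   `a_true_umol_m2_s`, `qin`, `tleaf_c`, `gsw_mol_m2_s`; attributes
#'   `true_params`, `config_id`, `noise_sd`, `seed`.
#' @export
generate_aci_curve <- function(true_params, config = model_config("M1121"),
                               stomatal = stomatal_params(), noise_sd = 0.3,
                               seed = 1,
                               env = leaf_env(irradiance = 2000),
                               ca_sequence = protocol_ca_sequence()) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(ca_sequence)), function(i) {
    e <- env
    e$ca <- ca_sequence$ca[i]
    r <- solve_coupled(e, true_params, config, stomatal)
    data.frame(obs = i, phase = ca_sequence$phase[i],
               ca_set_umol_mol = e$ca, ci_pa = r$ci,
               ci_umol_mol = co2_to_umol_mol(r$ci, e$pressure),
               a_true_umol_m2_s = r$a_net, qin = e$irradiance,
               tleaf_c = e$leaf_temp, gsw_mol_m2_s = r$gs,
               solver_ok = isTRUE(r$converged),
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  curve$a_umol_m2_s <- curve$a_true_umol_m2_s +
    stats::rnorm(nrow(curve), 0, noise_sd)
  curve <- curve[, c("obs", "phase", "ca_set_umol_mol", "ci_pa",
                     "ci_umol_mol", "a_umol_m2_s", "a_true_umol_m2_s",
                     "qin", "tleaf_c", "gsw_mol_m2_s", "solver_ok")]
  structure(curve, class = c("aci_curve", "data.frame"),
            true_params = true_params, config_id = config$model_id,
            noise_sd = noise_sd, seed = seed)
}

#' Read/write A-Ci curve CSV files
#'
#' Round-trip tabular interchange for measured or synthetic curves. The
#' reader requires the core columns (`ca_set_umol_mol`, `ci_pa`,
#' `a_umol_m2_s`) and tolerates any extra instrument columns.
#'
#' @param curve An `aci_curve` data.frame.
#' @param path File path.
#' @return `read_aci_csv` returns an `aci_curve` data.frame.
#' @export
write_aci_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aci_csv
#' @export
read_aci_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ca_set_umol_mol", "ci_pa", "a_umol_m2_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("A-Ci file lacks column(s): ", paste(missing, collapse = ", "))
  structure(df, class = c("aci_curve", "data.frame"))
}
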