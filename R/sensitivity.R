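#' Environmental scenario grid for the sensitivity analyses
#'
#' The factorial combination of atmospheric CO2 (280, 400, 600 umol/mol)
#' and incident light (200, 500, 1000 umol m-2 s-1) gives nine A-scenarios;
#' the CO2-response scenarios pair the preindustrial-to-present (280 to
#' 400) and present-to-future (400 to 600) steps with each light level,
#' giving six delta-A scenarios.
#'
#' @param ca_levels,i_levels Scenario levels (umol/mol; umol m-2 s-1).
#' @return List with `a_scenarios` (data.frame `ca`, `i`) and
#'   `delta_pairs` (data.frame `ca_low`, `ca_high`, `i`).
#' @export
scenario_grid <- function(ca_levels = c(280, 400, 600),
                          i_levels = c(200, 500, 1000)) {
  a <- expand.grid(ca = ca_levels, i = i_levels, KEEP.OUT.ATTRS = FALSE)
  a <- a[order(a$i, a$ca), , drop = FALSE]
  rownames(a) <- NULL
  pairs <- cbind(ca_levels[-length(ca_levels)], ca_levels[-1])
  d <- expand.grid(pair = seq_len(nrow(pairs)), i = i_levels,
                   KEEP.OUT.ATTRS = FALSE)
  d <- data.frame(ca_low = pairs[d$pair, 1], ca_high = pairs[d$pair, 2],
                  i = d$i)
  list(a_scenarios = a, delta_pairs = d)
}

#' Draw uniform parameter samples
#'
#' Independent uniform draws within the sensitivity-analysis ranges (no
#' covariance among parameters).
#'
#' @param n Number of draws.
#' @param ranges A data.frame as from [param_ranges()] (columns `name`,
#'   `low`, `high`).
#' @param seed Optional integer seed.
#' @return An `n` by `nrow(ranges)` matrix, columns named by parameter.
#' @export
sample_parameters <- function(n, ranges = param_ranges(), seed = NULL) {
  stopifnot(n > 0, all(ranges$low < ranges$high))
  if (!is.null(seed)) set.seed(seed)
  m <- vapply(seq_len(nrow(ranges)),
              function(j) stats::runif(n, ranges$low[j], ranges$high[j]),
              numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- ranges$name
  m
}

# parameter matrix (columns = 14 names) -> list of vectors for the kernel
mat_to_par <- function(m) {
  out <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(out) <- colnames(m)
  out
}

# Evaluate one model for all A-scenarios (and derived delta-A columns).
# Returns a matrix with one column per A-scenario then one per delta pair.
eval_scenarios <- function(par, config, scen, stomatal, iters = 50) {
  a <- vapply(seq_len(nrow(scen$a_scenarios)), function(s)
    as.numeric(solve_ci_vec(par, config, scen$a_scenarios$ca[s],
                            scen$a_scenarios$i[s], stomatal, iters = iters)),
    numeric(length(par[[1]])))
  if (length(par[[1]]) == 1) a <- matrix(a, nrow = 1)
  d <- vapply(seq_len(nrow(scen$delta_pairs)), function(s) {
    hi <- which(scen$a_scenarios$ca == scen$delta_pairs$ca_high[s] &
                scen$a_scenarios$i == scen$delta_pairs$i[s])
    lo <- which(scen$a_scenarios$ca == scen$delta_pairs$ca_low[s] &
                scen$a_scenarios$i == scen$delta_pairs$i[s])
    a[, hi] - a[, lo]
  }, numeric(nrow(a)))
  if (nrow(a) == 1) d <- matrix(d, nrow = 1)
  cbind(a, d)
}

scenario_labels <- function(scen) {
  data.frame(
    output = c(rep("A", nrow(scen$a_scenarios)),
               rep("deltaA", nrow(scen$delta_pairs))),
    ca = c(as.character(scen$a_scenarios$ca),
           paste0(scen$delta_pairs$ca_low, "-", scen$delta_pairs$ca_high)),
    i = as.character(c(scen$a_scenarios$i, scen$delta_pairs$i)),
    stringsAsFactors = FALSE)
}

#' Assimilation response to a CO2 step
#'
#' `deltaA = A(Ca_high) - A(Ca_low)` for one model and parameter set, both
#' states solved with the same parameters and hypotheses.
#'
#' @param config A [model_config()].
#' @param params A [photo_params()].
#' @param i_level Incident light (umol m-2 s-1).
#' @param ca_pair Length-2 vector `c(ca_low, ca_high)` (umol/mol).
#' @param stomatal A [stomatal_params()].
#' @return delta-A (umol CO2 m-2 s-1).
#' @export
delta_a <- function(config, params, i_level, ca_pair,
                    stomatal = stomatal_params()) {
  stopifnot(length(ca_pair) == 2)
  hi <- solve_coupled(leaf_env(ca = ca_pair[2], irradiance = i_level),
                      params, config, stomatal)
  lo <- solve_coupled(leaf_env(ca = ca_pair[1], irradiance = i_level),
                      params, config, stomatal)
  hi$a_net - lo$a_net
}

#' First-order parameter sensitivity analysis (Saltelli estimator)
#'
#' Two-matrix Saltelli scheme for first-order Sobol indices
#' `S_i = Var(E[Y|X_i]) / Var(Y)`, run per model configuration and
#' environmental scenario, for both the assimilation rate A and its CO2
#' response delta-A. Needs `n * (k + 2)` model executions per
#' configuration, where `k = 14` parameters.
#'
#' Integration across scenarios and configurations follows the
#' variance-weighting rule of [integrate_indexes()]: indices are weighted
#' by the output variance of each cell, means and variances are unweighted
#' averages.
#'
#' @param n Base sample size per matrix.
#' @param seed Integer seed.
#' @param configs Data.frame of configurations ([model_registry()] rows).
#' @param scen A [scenario_grid()].
#' @param stomatal A [stomatal_params()].
#' @param ranges Parameter ranges, [param_ranges()].
#' @param keep_outputs Keep the raw model outputs (needed for
#'   [bootstrap_convergence()]; memory grows as `n * (k + 2) * 15` doubles
#'   per configuration).
#' @return An object of class `sa_result` with elements `type`
#'   (`"parameter"`), `table` (long data.frame: `output`, `ca`, `i`,
#'   `model_id`, `mean`, `variance`, one index column per parameter;
#'   integrated rows labelled `"int"`), and `raw` (when kept).
#' @export
parameter_sa <- function(n, seed = 1, configs = model_registry(),
                         scen = scenario_grid(),
                         stomatal = stomatal_params(),
                         ranges = param_ranges(), keep_outputs = FALSE) {
  set.seed(seed)
  k <- nrow(ranges)
  ma <- sample_parameters(n, ranges)
  mb <- sample_parameters(n, ranges)
  labs <- scenario_labels(scen)
  ncell <- nrow(labs)
  idx_names <- ranges$name
  rows <- list()
  raw <- if (keep_outputs) list() else NULL
  for (cfg_i in seq_len(nrow(configs))) {
    config <- model_config(configs$model_id[cfg_i])
    fa <- eval_scenarios(mat_to_par(ma), config, scen, stomatal)
    fb <- eval_scenarios(mat_to_par(mb), config, scen, stomatal)
    fab <- vector("list", k)
    for (p in seq_len(k)) {
      mab <- ma
      mab[, p] <- mb[, p]
      fab[[p]] <- eval_scenarios(mat_to_par(mab), config, scen, stomatal)
    }
    if (keep_outputs)
      raw[[config$model_id]] <- list(fa = fa, fb = fb, fab = fab)
    cell <- data.frame(labs, model_id = config$model_id,
                       mean = NA_real_, variance = NA_real_,
                       stringsAsFactors = FALSE)
    S <- matrix(NA_real_, ncell, k, dimnames = list(NULL, idx_names))
    for (s in seq_len(ncell)) {
      y <- c(fa[, s], fb[, s])
      mu <- mean(y)
      cell$mean[s] <- mu
      v <- stats::var(y)
      cell$variance[s] <- v
      if (v <= 0) next  # degenerate output: indices undefined
      S[s, ] <- saltelli_first_order(fa[, s], fb[, s],
                                     lapply(fab, function(m) m[, s]))
    }
    rows[[config$model_id]] <- cbind(cell, S)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- add_integrated_rows(tab, idx_names)
  structure(list(type = "parameter", n = n, table = tab,
                 index_names = idx_names, raw = raw,
                 a = if (keep_outputs) ma else NULL,
                 b = if (keep_outputs) mb else NULL),
            class = "sa_result")
}

# integrated rows for a parameter-SA table: per model across scenarios,
# per scenario across models, and the grand row; variance-weighted indices,
# unweighted means/variances
add_integrated_rows <- function(tab, idx_names) {
  out <- list(tab)
  for (op in unique(tab$output)) {
    sub <- tab[tab$output == op, , drop = FALSE]
    for (m in unique(sub$model_id)) {
      g <- sub[sub$model_id == m, , drop = FALSE]
      out[[length(out) + 1]] <-
        integrated_row(g, idx_names, output = op, ca = "int", i = "int",
                       model_id = m)
    }
    for (s in seq_len(nrow(unique(sub[, c("ca", "i")])))) {
      key <- unique(sub[, c("ca", "i")])[s, ]
      g <- sub[sub$ca == key$ca & sub$i == key$i, , drop = FALSE]
      out[[length(out) + 1]] <-
        integrated_row(g, idx_names, output = op, ca = key$ca, i = key$i,
                       model_id = "int")
    }
    out[[length(out) + 1]] <-
      integrated_row(sub, idx_names, output = op, ca = "int", i = "int",
                     model_id = "int")
  }
  do.call(rbind, out)
}

integrated_row <- function(g, idx_names, output, ca, i, model_id) {
  ii <- integrate_indexes(g[, c("mean", "variance", idx_names)])
  data.frame(output = output, ca = ca, i = i, model_id = model_id,
             ii, stringsAsFactors = FALSE)
}

#' First-order Sobol indices from a Saltelli two-matrix design
#'
#' Estimates `S_i = Var(E[Y|X_i]) / Var(Y)` from model outputs on the base
#' matrices A and B and the hybrid matrices `A_B^i` (A with column i taken
#' from B): `S_i = mean(yb * (yab_i - ya)) / Var(Y)`, with all outputs
#' centred about the pooled sample mean of (A, B). Centring leaves the
#' expectation unchanged but removes the mean-squared-scale noise term of
#' the uncentred estimator.
#'
#' @param fa,fb Output vectors on the A and B matrices (length n).
#' @param fab List of output vectors on the `A_B^i` matrices, one per
#'   factor.
#' @return Vector of first-order indices, one per factor.
#' @export
saltelli_first_order <- function(fa, fb, fab) {
  mu <- mean(c(fa, fb))
  v <- stats::var(c(fa, fb))
  ya <- fa - mu
  yb <- fb - mu
  vapply(fab, function(yi) mean(yb * ((yi - mu) - ya)) / v, numeric(1))
}

#' Variance-weighted integration of sensitivity indices
#'
#' Integrates per-scenario sensitivity results into a single summary row:
#' the integrated index of each factor is the variance-weighted mean of the
#' per-scenario indices, `sum(V_e S_e) / sum(V_e)`; the integrated mean and
#' variance are unweighted arithmetic means of the per-scenario means and
#' variances.
#'
#' @param per_scenario Data.frame with columns `mean`, `variance` and one
#'   column per factor index.
#' @return One-row data.frame with the same columns.
#' @export
integrate_indexes <- function(per_scenario) {
  stopifnot(nrow(per_scenario) >= 1,
            all(c("mean", "variance") %in% names(per_scenario)))
  v <- per_scenario$variance
  if (sum(v) <= 0) stop("zero total variance: integrated indices undefined")
  idx <- setdiff(names(per_scenario), c("mean", "variance"))
  out <- data.frame(mean = mean(per_scenario$mean), variance = mean(v))
  for (nm in idx)
    out[[nm]] <- sum(v * per_scenario[[nm]]) / sum(v)
  out
}

#' Process-level sensitivity analysis (within- plus between-model variance)
#'
#' Variance-based sensitivity analysis whose factors are whole processes:
#' the composite factor of process `k` is its hypothesis choice together
#' with its member parameters. The first-order index is
#' `S_k = Var(E[Y | h_k, x_k]) / Var(Y)`, capturing both between-model
#' (hypothesis) and within-model (parameter) variation.
#'
#' Estimator: outer samples are stratified over the `m_k` hypotheses of the
#' process (uniform weight `1/m_k`), with `n` fresh draws of the process's
#' member parameters per stratum. The conditional mean of each outer sample
#' enumerates all `12/m_k` complementary hypothesis combinations with `n`
#' common draws of the remaining parameters (common random numbers across
#' strata and combinations). The total variance is computed from the full
#' set of ensemble executions (`4 * 12 * n^2` runs, each covering all
#' scenarios), in which all 12 models are equally represented.
#'
#' @inheritParams parameter_sa
#' @param keep_outputs Keep the per-outer-sample conditional means (needed
#'   for [bootstrap_convergence()]).
#' @return An `sa_result` with `type = "process"`; `table` has one row per
#'   scenario plus an integrated row per output, with index columns
#'   `carboxylation`, `electron_transport`, `tpu`,
#'   `limiting_rate_selection`.
#' @export
process_sa <- function(n, seed = 1, scen = scenario_grid(),
                       stomatal = stomatal_params(),
                       ranges = param_ranges(), keep_outputs = FALSE) {
  set.seed(seed)
  procs <- process_specs()
  registry <- model_registry()
  labs <- scenario_labels(scen)
  hyp_column <- c(carboxylation = NA, electron_transport = "etrans_hypothesis",
                  tpu = "tpu_included", limiting_rate_selection = "selection")
  spec <- lapply(names(procs), function(pk) {
    col <- hyp_column[[pk]]
    list(column = col,
         values = if (is.na(col)) list(NULL) else
           as.list(unique(registry[[col]])),
         ranges = ranges[ranges$name %in% procs[[pk]]$member_params, ,
                         drop = FALSE])
  })
  names(spec) <- names(procs)
  eval_model <- function(model_row, par)
    eval_scenarios(par, model_config(model_row$model_id), scen, stomatal)
  eng <- process_sa_engine(spec, registry, eval_model, n,
                           ncell = nrow(labs))
  S <- t(eng$numer) / eng$vtot  # ncell x nproc
  colnames(S) <- names(procs)
  tab <- cbind(data.frame(labs, model_id = "all", mean = eng$mu,
                          variance = eng$vtot, stringsAsFactors = FALSE), S)
  ints <- lapply(unique(tab$output), function(op)
    integrated_row(tab[tab$output == op, , drop = FALSE], names(procs),
                   output = op, ca = "int", i = "int", model_id = "all"))
  tab <- rbind(tab, do.call(rbind, ints))
  rownames(tab) <- NULL
  structure(list(type = "process", n = n, table = tab,
                 index_names = names(procs),
                 raw = if (keep_outputs)
                   list(condmeans = eng$condmeans, vtot = eng$vtot)
                 else NULL),
            class = "sa_result")
}

# Core stratified estimator of the process sensitivity indices, generic in
# the model set and evaluation function (exercised directly by the tests on
# toy systems with enumerable conditional means).
#
# `procs`: named list, one entry per process, each with
#   $column  name of the hypothesis column in `models` (NA if the process
#            has a single representation),
#   $values  list of hypothesis values (list(NULL) for single),
#   $ranges  data.frame (name, low, high) of the member parameters;
# `models`: data.frame of all hypothesis combinations (the model ensemble);
# `eval_model(model_row, par)`: returns an (n rows x ncell) output matrix
# for the parameter-vector list `par`.
#
# For each process: outer samples stratified over its hypotheses with n
# fresh member-parameter draws per stratum; conditional means enumerate the
# complementary hypothesis combinations with n common draws of the
# remaining parameters (common random numbers across strata and
# combinations). Total variance pools every execution, in which all models
# are equally represented.
process_sa_engine <- function(procs, models, eval_model, n, ncell) {
  all_ranges <- do.call(rbind, lapply(procs, `[[`, "ranges"))
  draws <- lapply(names(procs), function(pk) {
    rest <- all_ranges[!all_ranges$name %in% procs[[pk]]$ranges$name, ,
                       drop = FALSE]
    list(outer = lapply(procs[[pk]]$values, function(h)
           sample_parameters(n, procs[[pk]]$ranges)),
         inner = sample_parameters(n, rest))
  })
  names(draws) <- names(procs)
  io <- rep(seq_len(n), each = n)   # outer index of each lattice row
  ji <- rep(seq_len(n), times = n)  # inner index
  s1 <- s2 <- numeric(ncell)
  cnt <- 0
  numer <- matrix(NA_real_, length(procs), ncell,
                  dimnames = list(names(procs), NULL))
  condmeans <- list()
  for (pk in names(procs)) {
    col <- procs[[pk]]$column
    vals <- procs[[pk]]$values
    m_k <- length(vals)
    cm <- vector("list", m_k)  # per-stratum n x ncell conditional means
    for (h in seq_len(m_k)) {
      sub <- if (is.na(col)) models else
        models[models[[col]] == vals[[h]], , drop = FALSE]
      csum <- matrix(0, n, ncell)
      for (r in seq_len(nrow(sub))) {
        par <- c(
          mat_to_par(draws[[pk]]$outer[[h]][io, , drop = FALSE]),
          mat_to_par(draws[[pk]]$inner[ji, , drop = FALSE]))
        y <- eval_model(sub[r, , drop = FALSE], par)
        csum <- csum + rowsum(y, io, reorder = TRUE)
        s1 <- s1 + colSums(y)
        s2 <- s2 + colSums(y * y)
        cnt <- cnt + nrow(y)
      }
      cm[[h]] <- csum / (n * nrow(sub))
    }
    all_cm <- do.call(rbind, cm)  # (m_k * n) x ncell conditional means
    numer[pk, ] <- apply(all_cm, 2, stats::var)
    condmeans[[pk]] <- cm
  }
  names(condmeans) <- names(procs)
  mu <- s1 / cnt
  vtot <- (s2 / cnt - mu^2) * cnt / (cnt - 1)
  list(numer = numer, mu = mu, vtot = vtot, condmeans = condmeans,
       cnt = cnt)
}

#' Bootstrap standard deviations of sensitivity indices
#'
#' Resamples the stored ensemble outputs of a sensitivity run to estimate
#' the Monte-Carlo standard deviation of each per-scenario index.
#' Convergence is declared when every bootstrap SD is below 0.001. For the
#' process SA the outer conditional means are resampled within hypothesis
#' strata (the total-variance denominator, estimated from the full run, is
#' held fixed; its relative error is negligible beside the outer-sample
#' error). The run must have been made with `keep_outputs = TRUE`.
#'
#' @param sa_run An `sa_result` from [parameter_sa()] or [process_sa()].
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @return List with `sd` (matrix: scenario cells by factors) and
#'   `converged` (all SDs < 0.001).
#' @export
bootstrap_convergence <- function(sa_run, n_boot = 200, seed = 1) {
  stopifnot(inherits(sa_run, "sa_result"), n_boot >= 2)
  if (is.null(sa_run$raw)) stop("run the SA with keep_outputs = TRUE")
  set.seed(seed)
  if (sa_run$type == "process") {
    cm <- sa_run$raw$condmeans
    vtot <- sa_run$raw$vtot
    ncell <- length(vtot)
    reps <- array(NA_real_, c(n_boot, length(cm), ncell),
                  dimnames = list(NULL, names(cm), NULL))
    for (b in seq_len(n_boot)) {
      for (pk in names(cm)) {
        res <- lapply(cm[[pk]], function(mat)
          mat[sample.int(nrow(mat), replace = TRUE), , drop = FALSE])
        reps[b, pk, ] <- apply(do.call(rbind, res), 2, stats::var) / vtot
      }
    }
    sds <- apply(reps, c(2, 3), stats::sd)
    sds <- t(sds)
    colnames(sds) <- names(cm)
  } else {
    k <- length(sa_run$index_names)
    models <- names(sa_run$raw)
    ncell <- ncol(sa_run$raw[[1]]$fa)
    acc <- 0
    for (m in models) {
      r <- sa_run$raw[[m]]
      nn <- nrow(r$fa)
      reps <- array(NA_real_, c(n_boot, ncell, k))
      for (b in seq_len(n_boot)) {
        j <- sample.int(nn, replace = TRUE)
        for (s in seq_len(ncell)) {
          y <- c(r$fa[j, s], r$fb[j, s])
          mu <- mean(y)
          v <- stats::var(y)
          for (p in seq_len(k))
            reps[b, s, p] <-
              mean((r$fb[j, s] - mu) *
                     (r$fab[[p]][j, s] - r$fa[j, s])) / v
        }
      }
      acc <- acc + apply(reps, c(2, 3), stats::sd)
    }
    sds <- acc / length(models)
    colnames(sds) <- sa_run$index_names
  }
  list(sd = sds, converged = all(sds < 0.001, na.rm = TRUE))
}
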