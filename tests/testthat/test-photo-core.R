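test_that("gamma_star follows the kinetic-constant formula", {
  p <- photo_params(kc_half = 46, ko_half = 33, ko_kc_ratio = 0.21)
  e <- leaf_env(oi = 21)
  expect_equal(gamma_star(p, e), 0.21 * 46 * 21 / (2 * 33), tolerance = 1e-12)
  expect_equal(gamma_star(p, leaf_env(oi = 0)), 0)
  p2 <- photo_params(kc_half = 46, ko_half = 33, ko_kc_ratio = 0.42)
  expect_equal(gamma_star(p2, e), 2 * gamma_star(p, e))
  bad <- photo_params(); bad$ko_half <- -1
  expect_error(gamma_star(bad, e), "ko_half")
})

test_that("derived capacities scale linearly with vcmax25", {
  p <- photo_params(vcmax25 = 50, a_jv = 29.1, b_jv = 1.6355, b_tv = 0.167)
  d <- derive_dependent(p)
  expect_equal(d$jmax25, 29.1 + 1.6355 * 50)
  expect_equal(d$tpu25, 8.35)
  p2 <- photo_params(vcmax25 = 200, b_rv = 0.015)
  expect_equal(derive_dependent(p2)$rd, 3.0)
  # historical preset quotes Jmax and Rd directly
  pf <- photo_params("fvcb_original")
  expect_equal(derive_dependent(pf)$jmax25, 210)
  expect_equal(derive_dependent(pf)$rd, 1.1)
})

test_that("carboxylation-limited rate is Michaelis-Menten with O2 inhibition", {
  p <- photo_params(vcmax25 = 50, kc_half = 40.45, ko_half = 27.85)
  e <- leaf_env(oi = 21)
  km <- 40.45 * (1 + 21 / 27.85)
  expect_equal(ac_gross(40, p, e), 50 * 40 / (40 + km), tolerance = 1e-12)
  expect_equal(ac_gross(0, p, e), 0)
  expect_equal(ac_gross(1e9, p, e), 50, tolerance = 1e-6)
  expect_error(ac_gross(-1, p, e), "ci")
  # monotone increasing in Ci
  ci <- seq(0.1, 200, length.out = 50)
  expect_true(all(diff(ac_gross(ci, p, e)) > 0))
})

test_that("electron transport hypotheses behave as specified", {
  p <- photo_params(absorptance_a = 0.8, f_loss = 0.23)
  expect_equal(electron_transport(1000, p, "linear_cbgb"),
               0.8 * 0.5 * (1 - 0.23) * 1000)  # 308
  # Harley form saturates at jmax
  expect_equal(electron_transport(1e9, p, "hyperbola_harley"),
               derive_dependent(p)$jmax25, tolerance = 1e-4)
  # theta_j = 1 factorises into min(a alpha_i I, jmax)
  p1 <- photo_params(theta_j = 1)
  aai <- 0.8 * 0.5 * (1 - 0.23) * 1000
  expect_equal(electron_transport(1000, p1, "nonrect_fw"),
               min(aai, derive_dependent(p1)$jmax25), tolerance = 1e-9)
  # worked non-rectangular case, checked against the grid-search oracle
  p9 <- photo_params(vcmax25 = 50, theta_j = 0.9)
  j <- electron_transport(1000, p9, "nonrect_fw")
  expect_equal(j, root_oracle(0.9, aai, 110.875), tolerance = 1e-9)
  expect_equal(j, 105.4, tolerance = 1e-3)
})

test_that("RuBP-regeneration and TPU-limited rates follow their closed forms", {
  expect_equal(aj_gross(40, 110, 3.07), (110 / 4) * 40 / (40 + 2 * 3.07),
               tolerance = 1e-12)
  expect_equal(aj_gross(0, 110, 3.07), 0)
  expect_equal(aj_gross(1e9, 110, 3.07), 27.5, tolerance = 1e-6)
  # alpha_tpu = 0: net factor recovers exactly 3 TPU at any valid Ci
  for (ci in c(5, 12, 40, 90)) {
    ap <- ap_gross(ci, 8.35, 0, 3.07)
    expect_equal(ap * (1 - 3.07 / ci), 3 * 8.35, tolerance = 1e-12)
  }
  expect_equal(ap_gross(40, 8.35, 0.5, 3.07),
               3 * 8.35 * 40 / (40 - 2.5 * 3.07), tolerance = 1e-12)
  # inside the singular region the rate is flagged non-limiting
  expect_identical(ap_gross(7, 8.35, 0.5, 3.07), Inf)
  expect_identical(ap_gross(2.5 * 3.07, 8.35, 0.5, 3.07), Inf)
})

test_that("smaller_root matches the quadratic oracle and its limits", {
  expect_equal(smaller_root(1, 18, 24), 18, tolerance = 1e-12)
  expect_equal(smaller_root(0, 10, 10), 5, tolerance = 1e-12)
  expect_equal(smaller_root(0.95, 7, 7), 7 * (1 - sqrt(0.05)) / 0.95,
               tolerance = 1e-12)
  expect_error(smaller_root(1.2, 1, 1), "theta")
  set.seed(42)
  for (i in 1:1000) {
    theta <- runif(1)
    x1 <- runif(1, 0.01, 50)
    x2 <- runif(1, 0.01, 50)
    z <- smaller_root(theta, x1, x2)
    zo <- root_oracle(theta, x1, x2)
    expect_lt(abs(z - zo) / zo, 1e-9)
    expect_lte(z, min(x1, x2) + 1e-12)
  }
})

test_that("rate selection: minimum, two-stage smoothing, and labels", {
  cfg_min <- model_config("M1211")
  cfg_sm <- model_config("M1221")
  p <- photo_params(theta_cj = 0.95, theta_cjp = 0.98)
  s <- select_rate(18.0, 23.8, 31.0, cfg_min, p)
  expect_equal(s$a_gross, 18.0)
  expect_equal(s$limiting_state, "Ac")
  # smoothing with both thetas at 1 equals the minimum for random rates
  p1 <- photo_params(theta_cj = 1, theta_cjp = 1)
  set.seed(7)
  for (i in 1:50) {
    r <- runif(3, 1, 40)
    expect_equal(select_rate(r[1], r[2], r[3], cfg_sm, p1)$a_gross,
                 min(r), tolerance = 1e-9)
  }
  # triple co-limitation at the two-stage smoothing parameter values
  s77 <- select_rate(10, 10, 10, cfg_sm, p)
  expect_equal(s77$a_gross / 10, 0.77, tolerance = 0.005)
  # smoothing never exceeds the minimum
  set.seed(8)
  for (i in 1:50) {
    r <- runif(3, 0.5, 60)
    th <- runif(2, 0.05, 1)
    ps <- photo_params(theta_cj = th[1], theta_cjp = th[2])
    expect_lte(select_rate(r[1], r[2], r[3], cfg_sm, ps)$a_gross,
               min(r) + 1e-12)
  }
})

test_that("net assimilation applies photorespiration and respiration", {
  expect_equal(net_assimilation(18.03, 40, 3.07, 0.75),
               18.03 * (1 - 3.07 / 40) - 0.75, tolerance = 1e-12)
  expect_equal(net_assimilation(12, 3.07, 3.07, 0.9), -0.9)
  expect_equal(net_assimilation(12, 1e9, 3.07, 0), 12, tolerance = 1e-6)
  expect_error(net_assimilation(10, 0, 3, 0.5), "ci")
})

test_that("full demand-side chain: special-case equivalences over a Ci grid", {
  ci <- seq(3, 120, by = 3)
  e <- leaf_env(irradiance = 1000)
  p <- photo_params()
  # TPU inactive at low Ci: including it changes nothing
  lo <- ci[ci < 15]
  r1 <- assimilation_at_ci(lo, e, p, model_config("M1111"))
  r2 <- assimilation_at_ci(lo, e, p, model_config("M1211"))
  expect_equal(r1$a_net, r2$a_net, tolerance = 1e-12)
  # smoothing at theta = 1 reproduces the minimum model to machine precision
  p1 <- photo_params(theta_cj = 1, theta_cjp = 1)
  rmin <- assimilation_at_ci(ci, e, p1, model_config("M1111"))
  rsm <- assimilation_at_ci(ci, e, p1, model_config("M1121"))
  expect_equal(rsm$a_net, rmin$a_net, tolerance = 1e-12)
  # smoothing never exceeds the minimum: always on the gross rate, and on
  # the net rate above the compensation point (below it the negative
  # photorespiration factor flips the net-rate ordering)
  for (ids in list(c("M1111", "M1121"), c("M1213", "M1223"))) {
    rm_ <- assimilation_at_ci(ci, e, p, model_config(ids[1]))
    rs_ <- assimilation_at_ci(ci, e, p, model_config(ids[2]))
    expect_true(all(rs_$a_gross <= rm_$a_gross + 1e-12))
    above <- ci > rm_$gamma_star
    expect_true(all(rs_$a_net[above] <= rm_$a_net[above] + 1e-12))
  }
})

test_that("A is non-decreasing in Ci and irradiance for all 12 models", {
  p <- photo_params()
  reg <- model_registry()
  gs <- gamma_star(p, leaf_env())
  # above the TPU singular region but below the TPU takeover: with
  # alpha_tpu > 0 the TPU-limited state has a deliberately reversed Ci
  # sensitivity, so monotonicity holds only while Ac or Aj limit
  ci <- seq(2.5 * gs + 0.5, 60, length.out = 60)
  for (id in reg$model_id) {
    cfg <- model_config(id)
    a_ci <- assimilation_at_ci(ci, leaf_env(irradiance = 800), p, cfg)$a_net
    expect_true(all(diff(a_ci) > -1e-10), info = paste(id, "Ci"))
    a_i <- vapply(seq(50, 1900, by = 50), function(i)
      assimilation_at_ci(40, leaf_env(irradiance = i), p, cfg)$a_net,
      numeric(1))
    expect_true(all(diff(a_i) > -1e-10), info = paste(id, "I"))
  }
})

test_that("model registry has exactly 12 ids and round-trips", {
  reg <- model_registry()
  expect_equal(nrow(reg), 12)
  expect_equal(length(unique(reg$model_id)), 12)
  for (k in seq_len(nrow(reg))) {
    cfg <- model_config(reg$model_id[k])
    expect_equal(cfg$tpu_included, reg$tpu_included[k])
    expect_equal(cfg$selection, reg$selection[k])
    expect_equal(cfg$etrans_hypothesis, reg$etrans_hypothesis[k])
    rebuilt <- model_config(tpu_included = cfg$tpu_included,
                            selection = cfg$selection,
                            etrans_hypothesis = cfg$etrans_hypothesis)
    expect_equal(rebuilt$model_id, reg$model_id[k])
  }
  expect_error(model_config("M1311"), "invalid")
  expect_error(model_config("M2111"), "invalid")
})
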