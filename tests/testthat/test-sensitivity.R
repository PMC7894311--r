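test_that("parameter samples stay in range and are seed-reproducible", {
  m <- sample_parameters(5000, seed = 10)
  expect_true(all(m[, "vcmax25"] >= 45 & m[, "vcmax25"] <= 55))
  expect_true(all(m[, "theta_cj"] >= 0.81 & m[, "theta_cj"] <= 0.99))
  expect_true(all(m[, "theta_cjp"] >= 0.81 & m[, "theta_cjp"] <= 0.99))
  rng <- param_ranges()
  for (p in rng$name)
    expect_true(all(m[, p] >= rng$low[rng$name == p] &
                      m[, p] <= rng$high[rng$name == p]), info = p)
  expect_identical(m, sample_parameters(5000, seed = 10))
  expect_false(identical(m, sample_parameters(5000, seed = 11)))
})

test_that("the 14 parameters partition into the four processes", {
  pr <- process_specs()
  members <- unlist(lapply(pr, `[[`, "member_params"), use.names = FALSE)
  expect_setequal(members, param_ranges()$name)
  expect_equal(length(members), 14)
  expect_equal(vapply(pr, function(p) length(p$hypotheses), integer(1)),
               c(carboxylation = 1L, electron_transport = 3L, tpu = 2L,
                 limiting_rate_selection = 2L))
})

test_that("Saltelli estimator recovers closed-form indices of test functions", {
  # additive function: S_i = c_i^2 Var(X_i) / sum c_j^2 Var(X_j)
  set.seed(99)
  n <- 10000
  cc <- c(3, 2, 1, 0.5)
  lo <- c(0, -1, 2, 0); hi <- c(1, 1, 5, 10)
  draw <- function() vapply(1:4, function(j) runif(n, lo[j], hi[j]),
                            numeric(n))
  f <- function(m) drop(m %*% cc)
  A <- draw(); B <- draw()
  fab <- lapply(1:4, function(p) { AB <- A; AB[, p] <- B[, p]; f(AB) })
  S <- saltelli_first_order(f(A), f(B), fab)
  vi <- cc^2 * (hi - lo)^2 / 12
  expect_lt(max(abs(S - vi / sum(vi))), 0.01)

  # Ishigami function: analytic first-order indices
  a <- 7; b <- 0.1
  drawI <- function() matrix(runif(3 * n, -pi, pi), n, 3)
  fI <- function(m) sin(m[, 1]) + a * sin(m[, 2])^2 + b * m[, 3]^4 * sin(m[, 1])
  A <- drawI(); B <- drawI()
  fab <- lapply(1:3, function(p) { AB <- A; AB[, p] <- B[, p]; fI(AB) })
  S <- saltelli_first_order(fI(A), fI(B), fab)
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  vt <- v1 + v2 + b^2 * pi^8 * (1 / 18 - 1 / 50)
  expect_lt(abs(S[1] - v1 / vt), 0.02)
  expect_lt(abs(S[2] - v2 / vt), 0.02)
  expect_lt(abs(S[3]), 0.02)
})

test_that("parameters inactive in a configuration get an exactly zero index", {
  psa <- parameter_sa(n = 150, seed = 5)
  tab <- psa$table
  cell <- subset(tab, output == "A" & model_id == "M1111" & ca == "400" &
                   i == "500")
  # minimum selection, no TPU: smoothing and TPU parameters are unused
  for (p in c("theta_cj", "theta_cjp", "b_tv", "alpha_tpu"))
    expect_identical(cell[[p]], 0)
  # linear electron transport: jmax regression and theta_j are unused
  cell3 <- subset(tab, output == "A" & model_id == "M1113" & ca == "400" &
                    i == "500")
  for (p in c("a_jv", "b_jv", "theta_j"))
    expect_identical(cell3[[p]], 0)
  # but vcmax is active everywhere
  expect_gt(cell$vcmax25, 0.1)
})

test_that("process engine matches enumeration oracle on a toy two-process system", {
  f <- list(p1 = function(x) x, p2 = function(x) x^2)
  g <- list(q1 = function(y) 2 * y, q2 = function(y) sin(3 * y))
  models <- expand.grid(P = c("p1", "p2"), Q = c("q1", "q2"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  procs <- list(
    P = list(column = "P", values = list("p1", "p2"),
             ranges = data.frame(name = "x", low = 0, central = 0.5,
                                 high = 1)),
    Q = list(column = "Q", values = list("q1", "q2"),
             ranges = data.frame(name = "y", low = 0, central = 0.5,
                                 high = 1)))
  eval_model <- function(row, par)
    matrix(f[[row$P]](par$x) + g[[row$Q]](par$y), ncol = 1)
  set.seed(123)
  eng <- c3ensemble:::process_sa_engine(procs, models, eval_model,
                                        n = 2500, ncell = 1)
  S <- eng$numer[, 1] / eng$vtot

  # oracle: dense quadrature over the discrete-hypothesis lattice
  xs <- seq(0.5 / 4e3, 1 - 0.5 / 4e3, length.out = 4e3)
  fbar <- 0.5 * (f$p1(xs) + f$p2(xs))   # E over P-hypotheses at given x
  gbar <- 0.5 * (g$q1(xs) + g$q2(xs))
  mu <- mean(fbar) + mean(gbar)
  # conditional mean given (P-hypothesis, x) averages over Q entirely
  cm_p <- c(f$p1(xs) + mean(gbar), f$p2(xs) + mean(gbar))
  cm_q <- c(g$q1(xs) + mean(fbar), g$q2(xs) + mean(fbar))
  num_p <- mean((cm_p - mu)^2)
  num_q <- mean((cm_q - mu)^2)
  vals <- outer(c(f$p1(xs), f$p2(xs)), c(g$q1(xs), g$q2(xs)), `+`)
  vtot <- mean((vals - mu)^2)
  expect_lt(abs(S[["P"]] - num_p / vtot), 0.01)
  expect_lt(abs(S[["Q"]] - num_q / vtot), 0.01)
  expect_equal(eng$mu[1], mu, tolerance = 0.01)

  # identical hypotheses for Q: its index collapses to the purely
  # parametric index of its member parameter
  g2 <- list(q1 = function(y) 2 * y, q2 = function(y) 2 * y)
  eval2 <- function(row, par)
    matrix(f[[row$P]](par$x) + g2[[row$Q]](par$y), ncol = 1)
  set.seed(124)
  eng2 <- c3ensemble:::process_sa_engine(procs, models, eval2,
                                         n = 2500, ncell = 1)
  S2 <- eng2$numer[, 1] / eng2$vtot
  cm_q2 <- 2 * xs + mean(fbar)
  vals2 <- outer(c(f$p1(xs), f$p2(xs)), 2 * xs, `+`)
  expect_lt(abs(S2[["Q"]] -
                  mean((cm_q2 - mean(cm_q2))^2) /
                  mean((vals2 - mean(vals2))^2)), 0.01)
})

test_that("the two SA samplers agree on the ensemble mean and variance ordering", {
  psa <- parameter_sa(n = 150, seed = 21)
  prs <- process_sa(n = 40, seed = 22)
  gp <- subset(psa$table, output == "A" & ca == "int" & i == "int" &
                 model_id == "int")
  gq <- subset(prs$table, output == "A" & ca == "int" & i == "int")
  # equal means within Monte-Carlo error
  expect_equal(gp$mean, gq$mean, tolerance = 0.02)
  # between-model variance makes the process-SA total variance larger than
  # the within-model pooled parameter-SA variance
  expect_gt(gq$variance, 1.5 * gp$variance)
  # A at (600, 500) is right-shifted and wider than at (280, 500)
  lo <- subset(prs$table, output == "A" & ca == "280" & i == "500")
  hi <- subset(prs$table, output == "A" & ca == "600" & i == "500")
  expect_gt(hi$mean, lo$mean)
  expect_gt(hi$variance, lo$variance)
  # indices sum to at most ~1 (first-order only, estimator noise aside)
  idx <- as.matrix(gq[, prs$index_names])
  expect_lt(sum(idx), 1.15)
})

test_that("delta_a: zero for identical pair, positive CO2 response at high light", {
  p <- photo_params()
  cfg <- model_config("M1121")
  expect_equal(delta_a(cfg, p, 500, c(400, 400)), 0, tolerance = 1e-10)
  set.seed(33)
  m <- sample_parameters(25)
  for (r in seq_len(nrow(m))) {
    pr <- do.call(photo_params, as.list(m[r, ]))
    id <- sample(model_registry()$model_id, 1)
    expect_gt(delta_a(model_config(id), pr, 1000, c(280, 400)), 0)
  }
})

test_that("delta-A distributions split by the limiting-rate selection hypothesis", {
  set.seed(55)
  n <- 400
  m <- sample_parameters(n)
  par <- c3ensemble:::mat_to_par(m)
  d_by_sel <- function(ids) {
    d <- sapply(ids, function(id) {
      hi <- as.numeric(solve_ci_vec(par, model_config(id), 600, 500))
      lo <- as.numeric(solve_ci_vec(par, model_config(id), 400, 500))
      hi - lo
    })
    as.numeric(d)
  }
  reg <- model_registry()
  dmin <- d_by_sel(reg$model_id[reg$selection == "minimum"])
  dsm <- d_by_sel(reg$model_id[reg$selection == "quadratic_smoothing"])
  # conditioned on selection, the two modes are separated by more than the
  # within-group spread
  expect_gt(abs(mean(dmin) - mean(dsm)), max(sd(dmin), sd(dsm)))
})

test_that("integration rule: identity on one scenario, weights on many", {
  one <- data.frame(mean = 3.2, variance = 0.8, f1 = 0.4, f2 = 0.2)
  expect_equal(integrate_indexes(one), one)
  many <- data.frame(mean = c(2, 4), variance = c(1, 3),
                     f1 = c(0.2, 0.6), f2 = c(0.5, 0.1))
  out <- integrate_indexes(many)
  expect_equal(out$mean, 3)
  expect_equal(out$variance, 2)
  expect_equal(out$f1, (1 * 0.2 + 3 * 0.6) / 4)
  expect_equal(out$f2, (1 * 0.5 + 3 * 0.1) / 4)
  degenerate <- data.frame(mean = 1, variance = 0, f1 = 0.1)
  expect_error(integrate_indexes(degenerate), "variance")
})

test_that("bootstrap SDs are reproducible and shrink roughly as 1/sqrt(n)", {
  # additive test function packed into a parameter-type result object
  make_run <- function(n, seed) {
    set.seed(seed)
    cc <- c(2, 1, 0.5)
    draw <- function() matrix(runif(3 * n), n, 3)
    f <- function(m) drop(m %*% cc)
    A <- draw(); B <- draw()
    fab <- lapply(1:3, function(p) {
      AB <- A; AB[, p] <- B[, p]; matrix(f(AB), ncol = 1) })
    structure(list(type = "parameter", n = n,
                   index_names = c("c1", "c2", "c3"),
                   raw = list(m1 = list(fa = matrix(f(A), ncol = 1),
                                        fb = matrix(f(B), ncol = 1),
                                        fab = fab))),
              class = "sa_result")
  }
  small <- bootstrap_convergence(make_run(400, 1), n_boot = 120, seed = 9)
  small2 <- bootstrap_convergence(make_run(400, 1), n_boot = 120, seed = 9)
  expect_identical(small, small2)
  big <- bootstrap_convergence(make_run(6400, 1), n_boot = 120, seed = 9)
  ratio <- mean(small$sd) / mean(big$sd)  # expect ~ sqrt(16) = 4
  expect_gt(ratio, 2.4)
  expect_lt(ratio, 6.5)
  expect_error(bootstrap_convergence(make_run(100, 1), n_boot = 1), "n_boot")
})
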