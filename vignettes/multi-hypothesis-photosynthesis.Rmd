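---
title: "Methods: a multi-hypothesis C3 photosynthesis ensemble, its sensitivity analysis, and A-Ci curve inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-hypothesis photosynthesis ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model ensemble

Enzyme-kinetic models of C3 photosynthesis predict net CO2 assimilation
`A` (umol CO2 m-2 s-1) from the intercellular CO2 partial pressure `Ci`
(Pa) and incident light `I` (umol photons m-2 s-1). All members of the
ensemble share:

* net assimilation `A = A_g (1 - Gamma*/Ci) - R_d`, where the first factor
  accounts for photorespiratory CO2 release (so `A = -R_d` exactly at
  `Ci = Gamma*`) and `R_d` is dark respiration;
* the photorespiratory compensation point computed from RuBisCO kinetics,
  `Gamma* = (ko:kc) Kc Oi / (2 Ko)`, with `Kc` in Pa and `Oi`, `Ko` in kPa
  so the result is in Pa;
* the RuBisCO-limited (carboxylation) rate
  `A_c,g = Vcmax Ci / (Ci + Kc (1 + Oi/Ko))`;
* the RuBP-regeneration-limited rate `A_j,g = (J/4) Ci / (Ci + 2 Gamma*)`.

Three processes have competing representations:

1. **Electron transport** `J(I)`: (a) the smaller root of the
   non-rectangular hyperbola `theta_j J^2 - (a alpha_i I + Jmax) J +
   a alpha_i I Jmax = 0`; (b) the Harley saturating hyperbola
   `a alpha_i I / sqrt(1 + (a alpha_i I / Jmax)^2)`; (c) the linear form
   `J = a alpha_i I` with no maximum, as used by the Collatz (CBGB)
   model. Here `a` is leaf absorptance and `alpha_i = 0.5 (1 - f)` the
   intrinsic quantum efficiency (two photons per electron; `f` the
   fraction of absorbed photons lost before the photosystems).
2. **TPU limitation**: absent, or present as
   `A_p,g = 3 TPU Ci / (Ci - (1 + 3 alpha_tpu) Gamma*)`.
3. **Limiting-rate selection**: the strict minimum of the potential
   rates, or two-stage quadratic smoothing — the smaller root of
   `theta z^2 - (x1 + x2) z + x1 x2 = 0` applied first to
   `(A_c,g, A_j,g)` with `theta_cj` and then to the result and `A_p,g`
   with `theta_cjp`. At `theta = 1` the quadratic factorises into the
   minimum; at `theta = 0` it degenerates to the rectangular hyperbola
   `x1 x2 / (x1 + x2)`.

Carboxylation has a single representation, so the factorial gives
`1 x 2 x 2 x 3 = 12` models, labelled `M1xyz` (x TPU, y selection,
z electron transport).

Two published transcriptions of these equations circulate with ambiguous
operator signs; both are resolved here by internal-consistency arguments.
The TPU denominator is implemented with a minus sign because only then
does multiplying by the `(1 - Gamma*/Ci)` factor return exactly `3 TPU`
when `alpha_tpu = 0` (the closed-photorespiratory-cycle check). The
electron-transport quadratic is implemented in the standard
non-rectangular form given above because at `theta_j = 1` it must
factorise into `min(a alpha_i I, Jmax)`; both checks are enforced in the
test suite.

Capacities derive from `Vcmax,25` through widely used linear scalings:
`Jmax,25 = a_jv + b_jv Vcmax,25`, `TPU,25 = b_tv Vcmax,25`,
`R_d = b_rv Vcmax,25`. The two historical presets (`fvcb_original`,
`cbgb_original`) instead quote `Jmax` (210) and `R_d` (1.1) directly
where the original parameterisations did. Note that the CBGB original
quotes `f = 0.52`, which does not reproduce the Collatz intrinsic quantum
yield of 0.08 under `0.5 (1 - f)/4`; the printed `f` is used as given and
the discrepancy simply noted.

## Parameters, units, ranges

The 14 varied parameters (see `param_ranges()`) take commonly used
central values with +/-10% uniform sensitivity ranges, e.g. `Vcmax,25` =
50 (45–55) umol CO2 m-2 s-1, `Kc` = 40.45 Pa, `Ko` = 27.85 kPa, `ko:kc` =
0.21, `a` = 0.80, `f` = 0.23, `b_tv` = 0.167, `alpha_tpu` = 0.5, `b_rv` =
0.015. All three curvature parameters (`theta_j`, `theta_cj`,
`theta_cjp`) are centred at 0.9 (range 0.81–0.99): a +/-10% band around
the CBGB values 0.95/0.98 would leave the admissible interval [0, 1], so
a common central value of 0.9 keeps the design symmetric. The smoothing
analysis itself uses the CBGB values (and 0.9 as used by IBIS) directly.

Everything is a 25 degC reference value and no temperature response
functions are included — leaf temperature is fixed at 25 degC throughout,
which keeps the hypothesis comparison free of confounding temperature
models.

## Stomatal coupling

`Ci` is not prescribed in the ensemble runs; it solves the supply/demand
balance with the Medlyn unified stomatal model
`gs = g0 + 1.6 (1 + g1/sqrt(D)) max(A, 0)/Ca` (g1 = 4.3, the global C3
mean; g0 = 0.01 mol m-2 s-1; D = 1 kPa; boundary-layer and mesophyll
resistances zero) and supply `Ci = Ca - 1.6 A/gs` (mole fraction,
converted to Pa at 101.325 kPa unless overridden; `Oi` defaults to the
standard atmospheric 21 kPa). The solver is safeguarded bisection on the
supply-minus-demand residual: minimum-rule selection makes `A(Ci)`
non-smooth at rate transitions, which defeats Newton-type iterations,
while the residual always brackets a sign change between `Ci -> 0`
(supply exceeds demand) and `Ci = Ca + 1.6 R_d/g0` (the dark solution).
Fifty halvings put the bracket far below any measurement-relevant scale;
the scalar interface verifies `|residual| < 1e-8 Ca`. The quadratic roots
are computed in the multiply-by-conjugate form
`2 x1 x2 / (x1 + x2 + sqrt((x1+x2)^2 - 4 theta x1 x2))`, which is exact
at `theta = 0` and avoids catastrophic cancellation as `theta -> 0`.

Inside the TPU singular region `Ci <= (1 + 3 alpha_tpu) Gamma*` the
TPU expression is meaningless; `A_p,g` is returned as `+Inf` there so the
rate simply never wins selection, and low-Ci points still evaluate.

A consequence worth knowing: with `alpha_tpu > 0` the TPU-limited *net*
rate decreases with `Ci` (the deliberate "reversed sensitivity" of the
refined TPU formulation), so `A(Ci)` is monotone only while `A_c`/`A_j`
limit — at central parameters up to roughly 90 Pa, comfortably above the
scenario grid.

## Sensitivity analyses

Both analyses run over nine scenarios (Ca in {280, 400, 600} umol/mol
times I in {200, 500, 1000} umol m-2 s-1) and, for the CO2 response,
`deltaA = A(Ca_high) - A(Ca_low)` for the pairs 280→400 and 400→600 at
each light level, computed with common random numbers from the same model
executions.

**Parameter SA** uses the Saltelli two-matrix scheme for first-order
Sobol indices, per model and scenario (`n (k + 2)` runs per model,
k = 14). The estimator is centred about the pooled sample mean; centring
leaves its expectation unchanged but removes a Monte-Carlo noise term
proportional to the squared output mean which otherwise dominates at
realistic sample sizes. Parameters that a configuration does not use get
an exactly zero index, a structural property the tests assert.

**Process SA** treats a whole process — its hypothesis choice plus its
member parameters — as one composite factor, so its first-order index
`Var(E[Y | h_k, x_k]) / Var(Y)` captures between-model variance that
parameter SA cannot see. The estimator stratifies outer samples over the
process's hypotheses (uniform weights, n member-parameter draws per
stratum) and evaluates each conditional mean by enumerating the
complementary hypothesis combinations with n common draws of the
remaining parameters; the total variance pools all executions, in which
every model is equally represented. With four processes this costs
`4 * 12 * n^2` executions, each covering the full scenario grid in one
vectorised solve. Member parameters follow the process dependency
structure; the respiration scaling `b_rv` is grouped with carboxylation.
Hypothesis weights are uniform.

**Integration.** Per-scenario indices are combined as variance-weighted
means, `sum(V_e S_e) / sum(V_e)`; means and variances as unweighted
scenario averages. The same rule integrates parameter-SA indices across
the 12 models (weights = per-model variances). The rule is exercised
directly in the tests against a fixed nine-scenario reference table.

**Convergence.** `bootstrap_convergence()` resamples the stored outputs
and declares convergence when all index SDs fall below 0.001. Base sizes
of n = 300 (process) and n = 30,000 (parameter) satisfy this; the default
test runs use smaller n with correspondingly wider assertion tolerances
(process n = 150, parameter n = 3,000 in the acceptance tests; the
reproduction script runs 300 / 30,000).

## Smoothing analysis

The quadratics are scale-invariant, so the cost of smoothing at exact
co-limitation reduces to dimensionless scalars: `(1 - sqrt(1 - theta)) /
theta` for two equal rates, and the two-stage composition for three. At
the CBGB values (0.95, 0.98) the triple co-limitation scalar is 0.77
(23% reduction); two-rate reductions are 18% at 0.95, 9.1% at 0.99, 4.3%
at 0.998, and the triple reduction reaches 36% at the IBIS value 0.9 for
both stages. The two-stage ordering is fixed as `(A_c, A_j)` then `A_p`;
a single theta of 0.83 applied in this ordering does *not* reproduce the
38% reduction sometimes quoted for JULES-style parameterisations, so that
figure evidently assumes a different stage assignment and is not asserted
anywhere.

## Synthetic high-resolution A-Ci curves

`generate_aci_curve()` emulates a high-resolution gas-exchange protocol:
a conventional descending Ca leg (400, 300, 200, 150, 100, 75, 50
umol/mol), a return to 305 umol/mol followed by a fine scan in 5 umol/mol
steps to 1,000 (140 setpoints bracketing the co-limitation transition
zone), then a few larger steps (1,100–1,800). The descending and
high-extension setpoints are not standardised across instruments; the
defaults follow common practice and are configurable. At each setpoint
the coupled model yields `(Ci, A_true)` and the observation adds iid
Gaussian noise (default SD 0.3 umol m-2 s-1, typical closed-chamber
instrument noise). Irradiance is the saturating 2,000 umol m-2 s-1 of
such measurements. Generation and fitting share the 25 degC reference, a
deliberate simplification: the generator reproduces the statistical
structure the likelihood assumes (iid Gaussian residuals at known Ci),
not instrument drift, leak corrections or temperature artifacts — so
passing recovery tests demonstrates correctness of the inference
machinery, not robustness to real-instrument pathologies.

## Bayesian estimation of theta_cj

`fit_aci()` estimates `Vcmax,25`, `Jmax,25`, `theta_cj` and the residual
scale `sigma` from a curve. The fitted model is the two-limitation
(carboxylation, RuBP-regeneration) family with quadratic smoothing,
evaluated at each record's *measured* Ci — standard A-Ci practice, which
also makes the likelihood provably invariant to stomatal behaviour. TPU
is excluded from the fitted model; instead, records above the first
sustained decline of A with increasing Ca (five consecutive decreases of
the 5-point running mean) are removed first, so a TPU-affected high-CO2
tail cannot bias the estimates. Electron transport uses the
non-rectangular form with `theta_j` fixed at its central 0.9 — with the
saturating measurement irradiance the light term is effectively `Jmax`,
so this choice is inconsequential; `R_d` is tied to `Vcmax` via
`b_rv = 0.015` rather than sampled.

Priors are uniform: `Vcmax,25` in [100, 200], `Jmax,25` in [70, 400],
`theta_cj` in [0.9, 1.0]; `sigma` is a sampled nuisance parameter with a
uniform prior on [1e-3, 10] (its handling is otherwise unidentified by an
iid Gaussian error model).

The sampler is DREAM: 7 chains; proposals along summed difference vectors
of `delta` randomly selected chain pairs (delta uniform on 1–3, capped by
chain count), scaled by `gamma = 2.38 / sqrt(2 delta d')` with d' the
number of dimensions in the randomly drawn crossover subset; every fifth
generation `gamma = 1` to allow mode jumps; multiplicative jitter
U(-0.05, 0.05) and additive noise N(0, 1e-6); crossover probabilities
over CR in {1/3, 2/3, 1} adapted from normalised jump distances during
the first half; outlier chains (mean log-posterior over the second half
of history below Q1 - 2 IQR) reset to a healthy chain's state during
burn-in; proposals reflected at the prior bounds. These are conventional
DREAM hyper-parameters, declared here rather than asserted as unique.

Convergence uses the Gelman–Rubin R-hat on the post-burn-in halves with
threshold 1.1 (floored at 1, so identical chains report exactly 1); a
non-converged fit doubles the iteration budget once and otherwise
withholds summaries. Retained samples are thinned (default to 1%, mirror
of the full-scale protocol of 7 x 80,000 iterations with 25,000
post-convergence samples per chain); tests run 2,500–4,000 iterations
with 5% thinning, which the thinning-invariance test shows is
statistically equivalent for the posterior means. Calibration is checked
by a 50-replicate coverage study (truth `theta_cj = 0.99`, noise 0.3):
95% credible intervals cover the truth at the nominal rate within
binomial error. When the truth is the strict minimum (`theta_cj = 1`, on
the prior boundary), the posterior piles against 1 and the credible
interval includes it — the estimate is then read as "not distinguishable
from the minimum rule".

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`sample_parameters`,
`process_sa`, `parameter_sa`, `generate_aci_curve`, `dream_sample` are
bit-reproducible under a fixed seed). The analysis drivers default to the
convergence-checked sizes (process n = 300; parameter n = 30,000; 8,000
DREAM iterations for the synthetic fits); the test suite uses reduced
sizes chosen so each statistical assertion still holds with margin
against its stated tolerance.

## Known limitations

* No temperature response: everything is a 25 degC reference quantity.
* No mesophyll or boundary-layer resistance, no soil water limitation;
  the C4 pathway is out of scope.
* First-order sensitivity indices only; interactions are not decomposed
  (their aggregate share is visible as `1 - sum(S_i)`, around 5% here).
* The process-SA conditional means carry a small upward noise bias of
  order `Var_within / (n * 12/m_k)` relative to the total variance;
  at the default n this is far below the reported precision.
* The synthetic-data generator does not emulate instrument drift, leak
  corrections or match-valve artifacts; real-curve fits inherit whatever
  those do to the iid-residual assumption.
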