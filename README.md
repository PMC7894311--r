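# c3ensemble

Multi-hypothesis comparison of the two dominant enzyme-kinetic models of C3
leaf photosynthesis — the Farquhar–von Caemmerer–Berry (FvCB) family and the
Collatz (CBGB) family — as a tested R package plus a set of analysis
scripts.

The two model families share the same biochemical core but differ in three
places: the light response of electron transport (a saturating
non-rectangular hyperbola, a saturating Harley hyperbola, or the linear
CBGB form with no maximum), whether triose-phosphate-use (TPU) limitation
is simulated, and how the potentially limiting rates are combined — the
FvCB strict minimum

    A_g = min(A_c,g, A_j,g, A_p,g)

or the CBGB quadratic ("non-rectangular hyperbola") smoothing, the smaller
roots of

    theta_cj  * A_cj,g^2 - (A_c,g + A_j,g) A_cj,g + A_c,g A_j,g = 0
    theta_cjp * A_g^2    - (A_cj,g + A_p,g) A_g   + A_cj,g A_p,g = 0

Factorial combination of the alternatives gives a 12-member model ensemble
(`M1111` … `M1223`) over 14 parameters. The package implements:

* the full demand-side model (net assimilation from Ci, irradiance, O2),
  coupled to the Medlyn unified stomatal conductance model and solved for
  Ci by safeguarded bisection (`solve_coupled()`, `response_curve()`);
* variance-based **process sensitivity analysis** (factors = a process's
  hypothesis choice plus its parameters, capturing between- and
  within-model variance) and **parameter sensitivity analysis** (Saltelli
  two-matrix first-order Sobol indices), with variance-weighted
  integration across a 3 Ca x 3 I scenario grid (`process_sa()`,
  `parameter_sa()`, `integrate_indexes()`);
* closed-form analysis of the assimilation reduction that quadratic
  smoothing imposes relative to the minimum rule (`two_rate_scalar()`,
  `colimitation_scalar()`, `reduction_surface()`);
* a generator of synthetic high-resolution A–Ci curves (fine 5 umol/mol Ca
  scan across the co-limitation transition zone, iid Gaussian noise)
  (`generate_aci_curve()`);
* Bayesian estimation of `V_cmax,25`, `J_max,25` and `theta_cj` from A–Ci
  curves by the DREAM multi-chain MCMC sampler with Gelman–Rubin
  convergence checks (`dream_sample()`, `fit_aci()`).

## Worked example

```r
library(c3ensemble)

# coupled leaf state at 400 umol/mol CO2 and 1000 umol m-2 s-1 light
r <- solve_coupled(leaf_env(ca = 400, irradiance = 1000),
                   photo_params(), model_config("M1111"))
round(c(A = r$a_net, Ci_Pa = r$ci, gs = r$gs), 3)
#>      A  Ci_Pa     gs
#> 13.630 33.139  0.299
r$limiting_state
#> [1] "Ac"
```

At these conditions the leaf is RuBisCO-limited: net assimilation is
13.6 umol CO2 m-2 s-1 at an intercellular CO2 of 33.1 Pa, with stomatal
conductance 0.30 mol m-2 s-1.

```r
# how much does quadratic smoothing cost when all three rates co-limit?
s <- colimitation_scalar(0.95, 0.98)
round(as.numeric(s), 2); round(attr(s, "reduction_pct"))
#> [1] 0.77
#> [1] 23
```

With the CBGB curvature values (0.95, 0.98), smoothing multiplies gross
assimilation by 0.77 at exact triple co-limitation — a 23% reduction below
the strict minimum, i.e. an extra, purely empirical fourth limitation.

```r
# process sensitivity analysis at a reduced base sample size
ps <- process_sa(n = 100, seed = 7)
subset(ps$table, ca == "int")
#>    output  ca   i model_id mean variance carboxylation electron_transport
#> 16      A int int      all 11.5    2.658        0.2450              0.112
#> 17 deltaA int int      all  2.8    0.509        0.0471              0.141
#>       tpu limiting_rate_selection
#> 16 0.0186                   0.538
#> 17 0.0346                   0.631
```

Integrated across the nine CO2-by-light scenarios, the choice and
parameterisation of limiting-rate selection explains over half of the
ensemble variance in A — more than carboxylation, electron transport and
TPU combined.

## Analysis workflow

Numbered drivers under `analysis/` run the full study and write tidy CSV
tables under `results/`:

```sh
Rscript analysis/01_response_curves.R
Rscript analysis/02_smoothing_analysis.R
Rscript analysis/03_process_sa.R 300 1      # base n, seed
Rscript analysis/04_parameter_sa.R 30000 1
Rscript analysis/05_fit_synthetic_aci.R 8000 1
```

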