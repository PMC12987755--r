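# ipdtrend

Trend estimation in the 2PL item-response model when some common items
drift.

## The problem

Longitudinal assessments reuse overlapping dichotomous test forms and ask
how the latent ability distribution moved between two occasions. Under the
two-parameter logistic (2PL) model the probability of a correct response is

```
P_i(theta) = Psi(a_i * theta - d_i),     Psi(x) = 1 / (1 + exp(-x)),
```

the time-1 distribution is fixed at N(0, 1) for identification, and the
quantities of interest are the time-2 mean and SD, (mu2, sigma2). If a
sparse subset of common items drifts — its time-2 intercepts become
`d_i + delta_i` while discriminations stay invariant — estimators that
assume full invariance confound item drift with population change, and
same-signed ("unbalanced") drift biases the estimated trend.

`ipdtrend` is for psychometricians and methodologists who need
drift-resistant trend estimates or want to compare estimation strategies by
simulation. It implements, behind one tidy interface:

* **concurrent calibration** (`calibrate_concurrent()`) and **fixed
  calibration** (`calibrate_fixed()`) by marginal maximum likelihood (EM,
  compiled E-step);
* **robust Haberman and Haebara linking** of separate calibrations
  (`haberman_link()`, `haebara_link()`) with Lp losses `p = 0, 0.25, 0.5,
  1, 2` in smooth approximations, including the outlier-insensitive
  smooth-L0 loss;
* **drift detection and partial invariance**: RMSD statistics with fixed
  (0.03/0.05/0.08) or data-driven MAD cutoffs (tau = 1.7/2.7), one-step and
  iterative purification, all-other-anchor likelihood-ratio tests, and
  re-estimation on the surviving anchors (`detect_drift()`,
  `reestimate_partial_invariance()`);
* **regularized estimation**: per-item drift effects selected by direct
  minimization of a smooth BIC, `2 l* + log(N*) (H + sum x^2/(x^2+eps))`
  (`fit_regularized()`);
* a **simulation engine**: the 54-condition design (`sim_design()`), the
  126-estimator grid (`enumerate_estimators()`), replication runs and
  bias/RMSE evaluation (`run_replications()`, `evaluate_estimates()`),
  plus `run_simulate()` / `run_analyze()` and a thin CLI in
  `inst/cli/ipdtrend.R`.

Fits are plain tibble-friendly objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate the severest study condition — 20 items, N = 2,500 per occasion,
30% of items drifting by delta = -1.0 at time 2, true (mu2, sigma2) =
(1.0, 1.3) — and compare estimators:

```r
library(ipdtrend)

cond <- dplyr::filter(sim_design(), n == 2500, n_items == 20,
                      delta == 1, pct_ipd == 30, ipd_type == "unbalanced")
sim <- sim_responses(cond, seed = 7)

trend_estimates(sim$data,
                c("CC", "FC", "HAB-int(p=0)", "HAB-int(p=2)",
                  "HAE(normal0.5,p=2)", "REG(eps=0.001)"))
```

```
# A tibble: 6 x 5
  method               mu2 sigma2 converged settings
  <chr>              <dbl>  <dbl> <lgl>     <list>
1 CC                 1.26    1.24 TRUE      <named list [2]>
2 FC                 1.18    1.20 TRUE      <named list [2]>
3 HAB-int(p=0)       1.08    1.42 TRUE      <named list [3]>
4 HAB-int(p=2)       1.31    1.35 TRUE      <named list [3]>
5 HAE(normal0.5,p=2) 1.13    1.13 TRUE      <named list [4]>
6 REG(eps=0.001)     0.988   1.34 TRUE      <named list [2]>
```

The true time-2 mean is 1.0: concurrent and fixed calibration absorb the
drift (+0.26 and +0.18 here), squared-loss linking inherits it almost
fully, while the smooth-BIC regularized fit sits on the truth and the
smooth-L0 Haberman link close to it. The regularized fit also names the
drifting items:

```r
fit <- fit_regularized(sim$data)
dplyr::filter(tidy(fit), selected)
```

```
# A tibble: 6 x 5
  item      a      d  delta selected
  <chr> <dbl>  <dbl>  <dbl> <lgl>
1 I08   0.986 -0.435 -1.04  TRUE
2 I09   1.02  -0.469 -0.968 TRUE
3 I10   0.985 -0.460 -1.07  TRUE
4 I18   1.07  -0.478 -1.01  TRUE
5 I19   0.950 -0.424 -1.05  TRUE
6 I20   0.986 -0.439 -0.854 TRUE
```

(Numbers vary with the seed; these are from the exact call shown.)

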