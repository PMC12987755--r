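---
title: "Estimating ability trends under item parameter drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ability trends under item parameter drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal assessments estimate how a latent ability distribution moves
between two measurement occasions from overlapping dichotomous test forms.
Under the two-parameter logistic (2PL) model the probability of a correct
response to item $i$ is

$$P_i(\theta) = \Psi(a_i\theta - d_i), \qquad
\Psi(x) = \frac{1}{1 + e^{-x}},$$

with discrimination $a_i > 0$ and intercept $d_i$ (difficulty $b_i = d_i /
a_i$). The time-1 latent distribution is fixed at $\mathcal N(0, 1)$ for
identification; the targets of inference are the time-2 mean $\mu_2$ and SD
$\sigma_2$. When a sparse subset of common items drifts — their time-2
intercepts become $d_i + \delta_i$ while discriminations stay invariant
(uniform drift) — naive estimation confounds item drift with population
change. Drift is *balanced* when $\sum_{i} \delta_i = 0$ over common items
and *unbalanced* when all effects share a sign; unbalanced drift is the
damaging case.

`ipdtrend` implements five families of estimators of $(\mu_2, \sigma_2)$
under sparse uniform drift, together with the Monte-Carlo machinery to
compare them:

1. **Concurrent calibration (CC)** — joint two-group marginal ML with all
   common item parameters constrained equal (`calibrate_concurrent()`).
2. **Fixed calibration (FC)** — time-1 item parameters frozen for the
   time-2 fit; only $(\mu_2, \sigma_2)$ estimated (`calibrate_fixed()`).
3. **Robust linking** — separate per-occasion calibrations placed on a
   common scale by Haberman regression on log-discriminations and
   intercepts/difficulties (`haberman_link()`), or by Haebara IRF alignment
   (`haebara_link()`), with loss powers $p \in \{0, 0.25, 0.5, 1, 2\}$.
4. **Detection plus partial invariance** — drifting items flagged by the
   RMSD statistic (fixed cutoffs 0.03/0.05/0.08 or data-driven MAD cutoffs
   $\tau = 1.7, 2.7$) or by all-other-anchor likelihood-ratio tests, then
   re-estimation with the flagged items freed (`detect_drift()`,
   `reestimate_partial_invariance()`).
5. **Regularized estimation (REG)** — a joint model with a free drift
   effect per item, identified by directly minimizing a smooth BIC
   (`fit_regularized()`).

## Estimation machinery

All likelihood-based fits share one EM engine. The marginal likelihood
integrates the latent trait over a fixed standardized grid of 61 equally
spaced nodes on $[-6, 6]$ with weights proportional to the standard normal
density, renormalized; group-specific nodes are the affine images $\theta =
\mu_t + \sigma_t z$. Writing the model in terms of the standardized latent
variable $z$ makes every EM update a standard maximization of the expected
complete-data log-likelihood: per-item 2x2 (or, for the regularized model,
3x3) safeguarded Newton steps, and a 2x2 Newton step for $(\mu_2, \log
\sigma_2)$. Each update is accepted only if it does not decrease the
expected objective, so the observed-data deviance is monotone non-increasing
across iterations — an invariant the test suite asserts for every fit type.

Convergence is declared when the largest absolute parameter change falls
below `1e-5` (at most 1,000 iterations). The likelihood-ratio-test
alternative fits are the one exception: they warm-start from the constrained
baseline and stop when the deviance change drops below `1e-3`, because only
the deviance difference $G^2$ is consumed and it is compared against
$\chi^2_2$ critical values of 6–16; the residual optimization error
(≪ 0.01) is negligible at that scale while parameter-level iteration would
multiply the cost of a 20-item scan several-fold.

Items observed in only one category are excluded with a warning rather than
pushed to a boundary. Missing responses are ignorable: they simply drop out
of the likelihood product. Starting values are data-driven (logit
transforms of proportions correct; unit discriminations) — they affect
iteration counts, never the converged fit.

### Robust linking details

For $p = 2$ the Haberman steps have closed-form least-squares solutions,
which are used exactly. For $p < 2$ the losses are the smooth
approximations $(x^2+\epsilon)^{p/2}$ (centred at zero; $\epsilon = 0.001$)
and, for $p = 0$, $x^2/(x^2+\epsilon)$ with $\epsilon = 0.01$. These
objectives are nonconvex, so the profile over the linking constant is
minimized by a per-item candidate scan — every value that zeroes one item's
residual is a candidate basin — followed by local refinement; ties prefer
the smaller $|\mu_2|$. An independent grid-search oracle cross-checks the
optima in the tests.

The intercept residual in the Haberman mean step is $d_{i2} +
(a_{i2}/\sigma_2)\mu_2 - d_i$: under the scale transform $\theta^* =
\sigma_2\theta + \mu_2$, a time-2 intercept on its own scale maps to
$d^*_i - (a_{i2}/\sigma_2)\mu_2$, and solving for the joint intercept gives
exactly this residual. Because the SD step uses only log-discriminations,
it is algebraically untouched by intercept drift — a property asserted
bit-for-bit in the tests.

Haebara linking evaluates the weighted IRF discrepancy on 61 nodes over
$[-6, 6]$ of the time-2 scale; normal-density weights are centred at 0
(widths 0.5, 1, 2), the plausible choice given that each separate
calibration is identified at mean zero. The direction is asymmetric as
originally proposed (time-1 curves transformed onto the time-2 scale);
symmetric and information-weighted variants are out of scope. Optimization
is BFGS on $(\mu_2, \log\sigma_2)$ from multiple starts (identity, the
squared-loss Haberman solution and, for $p < 1$, its smooth-L0 analogue).

### Detection details

The RMSD for item $i$ at occasion $t$ is
$\mathrm{RMSD}_{it} = \sqrt{\int (\hat P_{it}(\theta) - P_i(\theta))^2
f_t(\theta)\, d\theta}$, where $P_i$ is the invariance-constrained IRF and
$f_t$ the model-implied normal density of occasion $t$. The square root is
part of the statistic: its name and the operating range of the conventional
cutoffs (0.03–0.08) both live on the root scale. $\hat P_{it}$ is the
pseudo-observed IRF — expected correct counts over expected exposure from
the converged E-step — the estimator used operationally in large-scale
assessment software. An item's flagging statistic is the larger of its two
per-occasion values; data-driven z-scores are computed per occasion (median
and MAD over the current anchor set, scale constant 1.4826) and an item is
flagged when it exceeds $\tau$ at either occasion. A degenerate MAD is
floored at $10^{-8}$, so ties produce z = 0 and genuine exceedances map to a
large capped score.

One-step detection computes statistics once under full invariance;
iterative detection re-fits the partial-invariance model each round,
recomputes statistics for remaining anchors only (flagged items are never
retested), and stops after at most 7 rounds. Whatever the statistic, at
least 3 of the common items must remain anchors; when more exceed the
threshold, the largest statistics win, ties broken toward the lower item
index for determinism. The likelihood-ratio test is one-step only — each
scan already costs one constrained fit plus one fit per item.

### Regularized estimation details

The smooth BIC is
$\mathrm{SBIC} = 2\,l^*(\mu_2,\sigma_2,a,d,\delta) + \log(N^*)\bigl(H +
\sum_i N_\epsilon(\delta_i)\bigr)$, with $l^*$ the negative marginal
log-likelihood, $N^* = N_1 + N_2$, $H = 2I + 2$ the count of non-penalized
parameters and $N_\epsilon(x) = x^2/(x^2+\epsilon)$ the smooth counter
(default $\epsilon = 0.001$; 0.01 and 0.0001 exposed). Minimization
alternates penalized per-item Newton updates of $(a_i, d_i, \delta_i)$ —
with the zero-profile solution always evaluated as a candidate, so effects
can land exactly in the zero basin — and Newton updates of $(\mu_2,
\log\sigma_2)$. Two starts are tried: the concurrent solution with all
$\delta_i = 0$, and separate-calibration differences after a robust L0
link; the lower SBIC wins. Because the smooth estimator never returns exact
zeros, `|delta| > 0.01` is the declared *reporting* convention for
"selected"; it has no role in estimation.

## The synthetic-data generator

`sim_responses()` generates the study conditions: time-1 abilities
$\mathcal N(0,1)$, time-2 abilities $\mathcal N(1.0, 1.3)$, responses
Bernoulli draws from the 2PL over a fixed bank of 10 base items (block-
replicated to 20 or 40), and additive intercept drift at time 2 on the
designated positions (item 10 of each block at 10%, items 8–10 at 30%,
all with unit discrimination). Unbalanced drift sets every affected effect
to $-|\delta|$; balanced drift alternates $+|\delta|, -|\delta|$ over the
affected items in index order, which satisfies the zero-sum definition
exactly — the alternation order is a package convention, chosen once so
runs are reproducible. The full crossed design (3 sample sizes × 2 test
lengths × drift size, percentage and type, with redundant no-drift cells
collapsed) has 54 conditions; the estimator grid has 126 configurations.

The generator emulates exactly what the comparison needs — correct 2PL
response processes, normal latent distributions, sparse uniform intercept
drift — and nothing else. Real assessment data add ingredients the
generator deliberately omits: nonuniform drift, misfitting response
functions, non-normal ability distributions, planned missingness, and
position or mode effects. Passing tests therefore certify the estimators'
behaviour under the stated model, not robustness to those violations.

Randomness is controlled by a single integer master seed; per-replication
child seeds are drawn once from it (`sample.int`), so any replication can
be regenerated in isolation.

## Problem sizes used by the checks

The packaged checks run the Monte-Carlo comparisons at reduced replication
counts chosen so each check's Monte-Carlo standard error is several times
smaller than the effect it verifies: 100–200 replications for the severe
unbalanced-drift biases (per-estimator SDs of roughly 0.04–0.11 give
standard errors of 0.003–0.011), and 80 replications for the no-drift
unbiasedness sweep across sixteen representative estimator configurations.
Parameter-recovery checks use single datasets of 100,000 persons, where
estimation error is below the asserted 0.01–0.02. The full-scale study
(1,000 replications everywhere) runs through the same
`run_simulate()` path by raising `reps`.

## Known limitations

A note on the smooth-L0 linking estimators at small samples: the package
computes the *global* minimizer of the smooth objective (the property the
oracle tests verify). With 500 persons per occasion, item-parameter noise
(standard errors of roughly 0.10–0.20 on intercepts and log-
discriminations) is comparable to the width of the L0 basins
($\sqrt\epsilon = 0.1$), so the global optimum behaves like a mode
estimator of noisy per-item link candidates: it is markedly more variable
than at large N, and in low-drift contaminated conditions its absolute
bias can exceed that of implementations that only locally refine a
least-squares start. Several alternative optimizers (two-start
quasi-Newton, $\epsilon$-annealed joint minimization, median-start local
refinement, converged IRLS) were evaluated during development; all behave
within a few hundredths of the global minimizer in these regimes, and the
global minimizer was kept because it is the declared estimand. At
N $\geq$ 1{,}000 the distinctions vanish.

* Two time points only; chained or joint linking across longer panels is
  out of scope, as are 1PL/3PL and polytomous models.
* Nonuniform drift (on discriminations) is not modelled; the regularized
  model penalizes intercept effects only.
* The quadrature grid is fixed, not adaptive; with extreme latent means
  (|mu| > 3) the default range should be widened via `em_control()`.
* Exact numerical agreement with other IRT software is not claimed — EM
  tolerances, quadrature schemes and optimizer paths differ — only
  statistical agreement at the reported Monte-Carlo precision.
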