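---
title: "Influence diagnostics for Poisson regression with the Liu estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence diagnostics for Poisson regression with the Liu estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liudiag)
```

## The model and its estimators

For counts $y_i$ with regressors $x_i \in \mathbb{R}^{p}$ (plus an intercept,
always the first coefficient), the Poisson log-linear model is
$y_i \sim \mathrm{Pois}(\mu_i)$, $\log \mu_i = x_i'\beta$. `poisson_fit()`
maximises the log-likelihood by Fisher scoring (IRLS): with weights
$\hat W = \mathrm{diag}(\hat\mu_i)$ and working response
$\hat z_i = \log\hat\mu_i + (y_i-\hat\mu_i)/\hat\mu_i$, iterate
$\hat\beta \leftarrow (X'\hat WX)^{-1}X'\hat W\hat z$ until the largest
coefficient change falls below `tol`.

Numerical choices: starting values $\hat\mu^{(0)}_i = y_i + 0.5$ (zero counts
are safe under the log link), `tol = 1e-8`, `max_iter = 50`, Cholesky solves
of $X'\hat WX$ with a hard error on rank deficiency, and an explicit
`converged = FALSE` state (carrying the last iterate) rather than a silent
wrong answer. The log-likelihood is monitored across iterations and a warning
is raised if it ever decreases. Zero counts use the $y\log y \to 0$
convention throughout, so deviance contributions are always well defined and
non-negative.

When regressors are collinear, $X'\hat WX$ is ill-conditioned and the ML
coefficients are unstable. The **Liu estimator**
$$\hat\beta_d = (X'\hat WX + I)^{-1}(X'\hat WX + dI)\,\hat\beta_{ML}, \qquad
0 \le d \le 1,$$
is a one-shot linear shrinkage of the ML solution with $\hat W$ frozen at the
ML fit; it is *not* re-iterated. In the eigenbasis
$X'\hat WX = \gamma\Lambda\gamma'$ each rotated coefficient is scaled by
$(\lambda_j + d)/(\lambda_j + 1)$, so $d = 1$ recovers ML exactly and $d = 0$
shrinks hardest; the map $d \mapsto \hat\beta_d$ is affine. By default the
intercept is shrunk together with the slopes (the transform uses the full
design matrix); `shrink_intercept = FALSE` restricts the transform to the
slope block, but the deletion diagnostics are defined only for the default.

`select_d()` implements the two data-driven rules
$$\hat d_1 = \max\Big(0, \min_j \tfrac{\alpha_j^2-1}{1/\lambda_j+\alpha_j^2}\Big),
\qquad
\hat d_2 = \max\Big(0, \min_j \tfrac{\alpha_j^2-1}{1/\lambda_j+\alpha^2_{\max}}\Big),$$
with $\alpha = \gamma'\hat\beta_{ML}$, additionally capped at 1 to respect
the $0 \le d \le 1$ constraint. Both rules return 0 as soon as any
$\alpha_j^2 < 1$; on strongly collinear designs (including the bundled
football data) that is the typical outcome, i.e. the rules choose maximal
shrinkage.

## Leverages, residuals and the diagnostic panel

The ML hat matrix is $H = \hat W^{1/2}X(X'\hat WX)^{-1}X'\hat W^{1/2}$
(symmetric, idempotent, $\mathrm{tr}\,H = p+1$); its Liu analogue is the
symmetric sandwich
$$H_d = \hat W^{1/2}X\,(X'\hat WX+I)^{-1}(X'\hat WX+dI)(X'\hat WX)^{-1}X'\hat W^{1/2},$$
a smoother rather than a projection, with
$0 \le h_{d,ii} \le h_{ii}$ for $d \in [0,1]$ and
$\mathrm{tr}\,H_d = \sum_j (\lambda_j+d)/(\lambda_j+1)$. (Because the
eigenvalue multiplier $(\lambda+d)/(\lambda+1)$ *increases* in $d$, the Liu
leverages increase towards the ML leverages as $d \to 1$; the package asserts
the verifiable bound $h_{d,ii} \le h_{ii}$ rather than any monotone decrease.)

The Pearson residual is taken as $\chi_i = (y_i-\hat\mu_i)/\sqrt{\hat\mu_i}$
— the form whose sum of squares is the Pearson statistic and the only one
consistent with the standardized and jackknife rescalings below. The
unsquare-rooted ratio $(y_i-\hat\mu_i)/\hat\mu_i$, which sometimes appears in
print as "the" Pearson residual, is exposed as
`residuals(fit, "pearson_raw")` but used nowhere downstream. Standardized:
$\chi_i' = \chi_i/\sqrt{1-h_{ii}}$; deviance: the signed root of the unit
deviance; jackknife: $t_i = \chi_i'\sqrt{(n-p-1)/(n-p-\chi_i'^2)}$, reported
as $\pm\infty$ when the radicand closes (an *infinite-influence flag*, never
an exception, and counted as a detection by the simulator). The two printed
variants of the jackknife numerator ($n-p-1$ versus $n-p'$ with $p' = p+1$
fitted coefficients) are the same number under this package's convention, so
there is a single implementation. Throughout, $p$ counts regressors
*excluding* the intercept.

For each estimator, `influence_table()` assembles:

| measure | formula | cutoff |
|---|---|---|
| Cook | $C_i = \chi_i'^2 h_{ii}/((p+1)(1-h_{ii}))$ | $4/(n-1)$ |
| $\Delta\chi^2_i$ | $\chi_i^2/(1-h_{ii}) = \chi_i'^2$ | 3.84 |
| $\Delta d^2_i$ | $d_i^2 + \chi_i^2 h_{ii}/(1-h_{ii})$ (default) or $d_i^2/(1-h_{ii})$ | 3.84 |
| DFFITS | $t_i\sqrt{h_{ii}/(1-h_{ii})}$, flagged on $|\cdot|$ | `dffits_cutoff()` |

3.84 is the 5% critical value of $\chi^2_1$. The two $\Delta d^2$ variants
(`dev_variant = "onestep"` / `"scaled"`) differ only through the
Pearson-versus-deviance residual in the leverage term; published detection
tables in this literature that show $\Delta\chi^2$ and $\Delta d^2$ agreeing
to the last digit are the signature of the `"scaled"` form. The classical
one-step form is the package default.

**The DFFITS cutoff is genuinely ambiguous in print.** The conventional rule
is $2\sqrt{(p+1)/n}$ (`form = "ratio"`, the package default), but the same
typographical string also reads as $2\sqrt{p+1}/n$ (`form = "over_n"`). On
the bundled football data the two differ by a factor of $\sqrt{n}$ (1.095
vs 0.245) and select very different flag sets; the `"over_n"` reading is the
one that reproduces the flag set published for these data exactly
({1, 6, 14, 19} under ML), so the worked example and the football tests pin
`dffits_form = "over_n"` while the default stays with the textbook rule.

## One-step deletion without refitting

For the ML fit, deleting observation $i$ from the *frozen* weighted
least-squares problem (weights and working response held at the full-data
fit) has the exact rank-one solution
$$\hat\beta_{ML} - \hat\beta_{ML(i)} =
(X'\hat WX)^{-1}x_i\,\hat W_{ii}^{1/2}\chi_i/(1-h_{ii}),$$
which is the classical one-step approximation to the refitted estimate.
Cook's distance is returned in its leverage form; the quadratic-form route
$(\Delta\hat\beta)'X'\hat WX(\Delta\hat\beta)/(p+1)$ is implemented
separately (`form = "displacement"`) and the two agree to $10^{-10}$ — an
algebraic identity the test suite enforces on random problems.

For the Liu estimator the deleted estimator is *defined* as
$$\hat\beta_{d(i)} = (X_{(i)}'\hat WX_{(i)}+I)^{-1}
(X_{(i)}'\hat WX_{(i)}+dI)\,\hat\beta_{ML(i)}.$$
With $K = \hat W^{1/2}X$ and $k_i$ its $i$-th row, the only inverse that
changes is $(K'K+I)^{-1}$, and the Sherman–Morrison–Woodbury theorem gives it
in closed form:
$$(K_{(i)}'K_{(i)}+I)^{-1} = (K'K+I)^{-1} +
\frac{(K'K+I)^{-1}k_i'k_i(K'K+I)^{-1}}{1-m_{di}}, \qquad
m_{di} = k_i(K'K+I)^{-1}k_i'.$$
`one_step_delete(liu_fit, i, method = "exact")` (the default) evaluates this
definition directly — still strictly one-step, no refit — and therefore
reduces *exactly* to the ML one-step at $d = 1$. The deletion leverage pair
$(m_i, m_{di})$ with $m_i = h_{ii}$ and $0 \le m_{di} < m_i < 1$ is exposed
by `deletion_leverages()`.

A compact single-expression form,
$$\hat\beta_d - \hat\beta_{d(i)} =
(X'\hat WX+I)^{-1}x_i\,\hat W_{ii}^{1/2}\chi_{di}/(1-m_{di}),$$
is available as `method = "collapsed"`. It vanishes exactly when the Liu
Pearson residual $\chi_{di}$ is zero, which the exact form does not (deleting
a perfectly-fitted row still perturbs the shrinkage transform through
$X'\hat WX$), but it does **not** reduce to the ML one-step at $d = 1$: its
prefactor keeps $(X'\hat WX+I)^{-1}$ and $m_{di}$ where the ML formula has
$(X'\hat WX)^{-1}$ and $h_{ii}$. No single expression can have both
properties; the package defaults to the exact form because the $d = 1$ limit
is the identity that anchors the whole Liu panel to its ML counterpart (the
estimators coincide there, so their diagnostics should too), and because the
exact form is what the rank-one update actually implies for the deleted
estimator as defined. Both forms agree with brute-force row deletion of the
frozen problem to $10^{-10}$ in their respective senses, which the test suite
checks directly.

The Liu panel substitutes $\hat\mu_{di} = \exp(x_i'\hat\beta_d)$,
$\chi_{di}$, and $h_{d,ii}$ into the four measures; the deletion denominator
uses $m_{di}$, which is a different quantity from $h_{d,ii}$ — conflating
them changes results, so both are carried in the Liu influence table. The
Liu Cook's distance defaults to the plain quadratic form
$(\Delta\hat\beta_d)' X'\hat WX (\Delta\hat\beta_d)/(p+1)$; a sandwich
variant with middle matrix
$(X'\hat WX+I)(X'\hat WX+dI)^{-1}X'\hat WX(X'\hat WX+dI)^{-1}(X'\hat WX+I)$
is exposed as `form = "sandwich"` and coincides with the plain form at
$d = 1$. The shrinkage parameter is held at its full-data value for all
deletion diagnostics; re-selection happens only in exact-refit impact
reports, below.

## Deletion impact reports

`deletion_impact()` answers the applied question "how much do the
coefficients move when these observations are dropped?" as
$100\,|\hat\beta_{full}-\hat\beta_{del}|/|\hat\beta_{full}|$ per coefficient.
The default mode refits from scratch on the reduced data (the only
construction that supports multi-observation sets); `one_step` mode uses the
closed-form changes for single deletions. For the Liu estimator the reduced
fit either re-selects $d$ by the same rule (`d_policy = "refit_d"`, default)
or holds the full-data value (`"hold_d"`); both are provided because applied
reports rarely state which was done. Percentage changes explode when a
full-data coefficient is near zero — a warning is raised, because values in
the thousands of percent are then expected arithmetic, not errors.

## The football data: conventions pinned by the worked example

The bundled `english_league()` table (20 club-seasons, response = matches
won, five collinear club statistics) is this package's worked example, and
three conventions are pinned against published results for these data:

* **Condition index.** `condition_index()` offers the correlation form of
  the regressors (default; 18.024 here), the raw cross-product with
  intercept, the ML-weighted cross-product, and the correlation form of the
  *full* table including the response (`"correlation_all"`). The condition
  index published for these data (31.274) is not reproduced by any
  regressor-only convention we could construct; the full-table correlation
  form comes closest (31.641, within ~1.2%) and is therefore the documented
  match, with the discrepancy stated rather than hidden.
* **DFFITS cutoff.** As above, `"over_n"` reproduces the published ML flag
  set {1, 6, 14, 19} exactly; the textbook rule flags only {1}.
* **Coefficient labels in deletion impacts.** Exact-refit deletion of
  observations 1, 19, and {1, 19} reproduces the published percentage
  changes for the intercept and four of the five slopes to the printed 0.1 —
  but the published values for the third slope are carried by the *fourth*
  regressor column of the table as printed (e.g. 77.7% after deleting
  observation 19). The two middle column labels are evidently transposed in
  the source material; the package keeps the printed column order and the
  documentation points the published $\beta_3$ values at `x4`. One published
  column (144.7 / 70.5 / 13.9) matches no quantity we can compute and is not
  asserted anywhere.

The published *Liu* flag sets for these data ({1, 19} on Cook,
$\Delta\chi^2$, $\Delta d^2$; eleven observations on DFFITS) are **not**
reproducible from the estimator as defined, under any $d \in [0,1]$, any
residual convention consistent with the formulas above, or either deletion
method: at maximal shrinkage ($d = 0$, which both selection rules choose
here) the largest Liu $\Delta\chi^2$ on these data is 0.95, far below the
3.84 cutoff, and $d = 1$ is exactly ML, which flags nothing on those
measures. The package reports what the formulas give — Cook flags {1}, the
chi-square and deviance measures flag nothing, DFFITS (at the pinned cutoff)
flags {1, 6, 8, 18, 19} — and the football tests freeze these as regression
values.

## The Monte Carlo detection study

`simulation_spec()` + `run_cell()`/`run_grid()` implement the standard
detection experiment for a planted influential observation:

1. $z_{ij}$ i.i.d. standard normal, $n \times (p+1)$;
   $x_{ij} = \sqrt{1-\rho^2}\,z_{ij} + \rho\,z_{i,p+1}$, so every pair of
   regressors has population correlation $\rho^2$ (the controlled
   collinearity level).
2. Counts $y_i \sim \mathrm{Pois}(\exp(\beta_0 + x_i'\beta))$ with
   $\sum\beta_j^2 = 1$. Defaults $\beta_j = 1/\sqrt p$, $\beta_0 = 0$ — the
   simplest members of the stated constraint; detection rates are sensitive
   to this choice, so it is fixed once and documented here.
3. One row (index 15 by default) is shifted by $\bar x_j + 6$ in every
   regressor. By default the shift happens **after** the counts are drawn
   (`inject = "post_response"`): the planted row is a severe leverage point
   whose count disagrees with its shifted regressors, which is the only
   construction under which residual-based measures ($\Delta\chi^2$,
   $\Delta d^2$) have non-trivial power. The generative alternative
   (`"pre_response"`), in which the count is drawn from the shifted row, is
   provided for comparison: the fit then accommodates the high-leverage row
   and the chi-square measures sit at their ~5% null rate while
   leverage-driven measures still fire — a contrast the test suite checks.
4. Per replication: IRLS fit, $d$ by the chosen rule, Liu fit, all eight
   diagnostics evaluated at the planted row, detection = that row exceeds the
   measure's cutoff (an infinite statistic counts as a detection).
   Non-converged replications are discarded and reported in
   `n_failed_fits`; percentages are over converged replications, with
   binomial Monte Carlo standard errors.

Reproducibility: one master seed per cell; each replication draws its own
substream seed, so cells are independently reproducible and two runs with the
same spec are identical.

At the default settings the planted shift is extreme — roughly six regressor
standard deviations in every column, moving the linear predictor by about
$6\sqrt p$ — and all eight measures detect it in essentially every
replication (the acceptance script prints the exact percentages). Published
detection tables for this design report substantially lower and more
heterogeneous rates (e.g. 47–96% in the smallest cell), which under the
stated design would require a much milder contamination or additional
unstated scalings; sweeps over injection timing, uniform generators,
standardization and no-intercept fits reproduced neither those levels nor a
Liu-above-ML ordering. A correctly implemented Liu panel detects *slightly
less* than ML at strong shrinkage, because shrinkage damps exactly the
leverage that the diagnostics measure. The simulator therefore demonstrates
internal properties — determinism, the null behaviour of generative
injection, trend stability in $n$ — rather than matching any particular
published table, and the tests are written accordingly.

What the generator does *not* emulate about real count data: overdispersion,
zero inflation, discrete or skewed regressors, multiple simultaneous
outliers, and model misspecification. Passing detection tests therefore
bounds what can be claimed: they show the one-step formulas flag a planted
gross contamination under clean Poisson sampling, not that the cutoffs are
calibrated for messy data.

## Known limitations

* One influential case at a time: the one-step formulas are rank-one, and
  masking among multiple outliers is out of scope (exact refits via
  `deletion_impact()` are the fallback).
* No offsets, exposures, overdispersion models or non-canonical links; the
  design matrix is explicit (no formula interface).
* The Liu deletion diagnostics require the intercept to be part of the
  shrinkage transform (the default).
* Cutoffs are the conventional constants; they are not recalibrated for the
  Liu estimator, matching practice in this literature.
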