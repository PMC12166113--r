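---
title: "Pseudo-score changepoint testing and power analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-score changepoint testing and power analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorecp)
```

## The problem

A sequence of observations $y_1, \dots, y_n$ — gene-dosage ratios ordered
along a chromosome, yearly assessment means, the 0/1 item scores of one
examinee during a computerized adaptive test — may change regime abruptly
at an unknown position.  Two regression forms cover the cases handled
here, both written as

$$ g\{E(y_i)\} = x_i^{\mathsf T}\beta + \delta\,\varphi(z_i, \psi), $$

where $z$ is the ordered covariate (by default the scaled index $i/n$),
$\psi$ the unknown changepoint and $\delta$ the effect of the change:

* the **jump-point model**, $\varphi(z,\psi) = I(z > \psi)$: a level shift,
  the classical change-in-mean setting;
* the **segmented (broken-line) model**,
  $\varphi(z,\psi) = (z-\psi)_+$: two straight lines joined at $\psi$,
  with slope difference $\delta$.

Testing for the existence of the changepoint is testing
$H_0\colon \delta = 0$.  The difficulty is that $\psi$ vanishes under
$H_0$, so classical likelihood-ratio statistics have nonstandard limiting
distributions and tabulated or simulated critical values.

## The pseudo-score statistic

The package's central quantity sidesteps the vanishing parameter by
averaging the changepoint basis over $K$ fixed candidate values
$\psi_1 < \dots < \psi_K$:

$$ \bar\varphi_i = K^{-1}\sum_{k=1}^K \varphi(z_i, \psi_k), \qquad
   s_0 = \frac{\bar\varphi^{\mathsf T}(I_n - A)\,y}
              {\{\sigma^2\,\bar\varphi^{\mathsf T}(I_n - A)\,\bar\varphi\}^{1/2}}, $$

where $A$ is the hat matrix of the null fit.  Since $\bar\varphi$ is a
fixed vector, $s_0$ is an ordinary standardized linear contrast of the
null residuals: exactly $N(0,1)$ under $H_0$ for gaussian errors with
known $\sigma^2$, and asymptotically so — with fast convergence — when
$\sigma^2$ is estimated or the response is binomial.  Under a broken-line
alternative the mean shifts to

$$ E_1[s_0] = \frac{\delta\,\bar\varphi^{\mathsf T}(I_n - A)(z-\psi)_+}
                   {\{\sigma^2\,\bar\varphi^{\mathsf T}(I_n - A)\bar\varphi\}^{1/2}} $$

while variance and normality are preserved, which is what makes analytic
power and sample-size planning possible (`seg_power`, `seg_sample_size`).

### The null design: jump versus broken line

A point that matters in practice and that the function defaults encode:

* For the **jump** test (`pscore_test`, default `kind = "jump"`), the null
  model is the design the user supplies — by default intercept only,
  matching the jump-point model in which the covariate has no effect
  under $H_0$.
* For the **broken-line** power analysis (`expected_s0_h1`, `seg_power`),
  the null design is the straight line $[1, z]$.  The linear component of
  the alternative $(z-\psi)_+$ belongs to the null model; projecting it
  out is what gives power calculations their meaning.  With an
  intercept-only null the same formula would count the linear trend as
  evidence of a changepoint and overstate power dramatically (for the
  reference design below, 0.999 rather than 0.749).

The averaged jump basis on an equispaced covariate is itself close to
linear in $z$, so a jump test *against a linear null* has little power by
construction; users who include $z$ in `X` should do so deliberately.

## Defaults and tunable parameters

* **Candidate grid** (`K = 10`): equally spaced quantiles of $z$ between
  its 10th and 90th percentiles (`default_psi_grid`).  Trimming keeps
  candidates away from the boundaries, where a changepoint is confounded
  with the intercept; 10 candidates are enough that the averaged basis is
  insensitive to the exact placement (the reference power below moves by
  less than 0.001 across reasonable grid variants).  `psi_grid` overrides
  the default.
* **Variance source** (`sigma2_source = "h0_estimate"`): residual
  variance of the null fit with divisor $n - p$.  `"h1_estimate"` uses
  the null design augmented with $\bar\varphi$ (divisor $n - p - 1$);
  `"known"` takes a supplied value.  The binomial family needs none — the
  variance function $\mu(1-\mu)$ at the null fit plays the role of
  $\sigma^2$ inside the weighted quadratic form.
* **Alternative**: `two.sided` ($p = 2\{1 - \Phi(|s_0|)\}$), `greater`,
  `less` (signed tails).
* **Changepoint location estimate**: the candidate maximizing the squared
  single-candidate statistic, ties to the smallest candidate.  For the
  jump basis the statistic is constant between data points, so the
  profile grid is the set of midpoints between consecutive distinct $z$
  values, trimmed to the 10–90 percentile band.
* **Levels**: test functions default to $\alpha = 0.05$; power functions
  default to $\alpha = 0.01$.

## The classical benchmarks

`wmax_test` scans every split $j$ and takes
$\max_j |t_{jn}|$ of the pooled two-sample $t$ on $n-2$ degrees of
freedom.  Its critical values are tabulated for $n \in [10, 50]$ at
levels 0.10/0.05/0.01 and linearly interpolated in $n$ (e.g. 3.344 at
$n = 16$, $\alpha = 0.05$); outside the tabulated range the function
refuses rather than extrapolates.

`lmax_test` handles binary Rasch sequences with known (calibrated) item
difficulties: for each split in the trimmed range $[n_1, n - n_1]$, with
$n_1$ the nearest integer to $0.15\,n$ (ties away from zero), it compares
segment-wise ability MLEs with the pooled MLE,
$L_{jn} = 2\{\ell(\hat\theta_1) + \ell(\hat\theta_2) - \ell(\hat\theta_0)\}$,
and rejects when $\max_j L_{jn} > 8.85$ (the tabulated value for trimming
fraction 0.15 at $\alpha = 0.05$, the only tabulated level).  Ability
maximization is bounded to $[-6, 6]$ (tolerance $10^{-8}$): all-correct /
all-incorrect segments have divergent MLEs, and the bound — far outside
the $N(0,1)$ ability range of the simulation design — caps them while
flagging the boundary hit.

## Synthetic data generators

The two generators are the study designs under which the package's
operating characteristics are measured:

* `gen_normal_jump(n, delta)`: $y_i = 2 + \delta\,I(z_i > 0.5) +
  \varepsilon_i$, $z_i = i/n$, standard gaussian errors.
* `gen_binary_cat(n, delta)`: item difficulties $b_i \sim N(0,1)$;
  ability $\theta_1 \sim N(0,1)$ up to the changepoint item (11, 15, 21,
  25 for $n$ = 20, 30, 40, 50; midpoint otherwise), $\theta_2 = \theta_1 +
  \delta$ afterwards; scores Bernoulli with the Rasch probability
  $\mathrm{logit}^{-1}(\theta - b_i)$.

`run_study` crosses these with the three tests at $\alpha = 0.05$ and
records rejection fractions; each cell runs under an independent seed
derived from the master seed and recorded in the output, so any cell can
be re-run exactly.  Degenerate replicates (all-0/all-1 binary patterns,
constant responses) are kept and counted as non-rejections through the
tests' degenerate paths.

What the generators do **not** emulate: serial correlation, heteroscedastic
or heavy-tailed errors, item-difficulty adaptivity of a real CAT (the
difficulties here are independent of the interim ability estimate),
multiple changepoints, and gradual rather than abrupt drifts.  Calibration
and power results under these designs therefore do not certify behaviour
under such departures.

## Numerical and degenerate-input choices

* Degenerate statistics (constant response with an estimated variance;
  $\bar\varphi$ inside the column span of the null design) return
  $s_0 = 0$, $p = 1$ with a `"degenerate"` flag instead of erroring, so
  long simulation loops survive.
* The broken-line fitter `fit_segmented` profiles the residual sum of
  squares over a grid of interior data values and midpoints (the ramp
  basis varies continuously in $\psi$, and least-squares breakpoints often
  sit on observed covariate values), then reports the covariance of
  $(\hat\delta, \hat\psi)$ from the working linear model augmented with
  the changepoint-derivative column $-\hat\delta\,I(z > \hat\psi)$.  A
  flat profile (no curvature evidence) yields a warning and a
  widest-uncertainty covariance with the squared half-range of $z$ as the
  changepoint variance.
* Post-experimental power (`postexp_power`) plugs
  $(\hat\delta, \hat\psi, \hat\sigma)$ into the analytic formula on the
  observed covariate; the optional interval draws parameters from the
  bivariate normal at the fitted covariance, redrawing (up to 10 times,
  then clamping just inside the range) draws whose changepoint leaves the
  covariate range.
* Distribution-based covariates are realized at the mid-probabilities
  $p_i = (i - 0.5)/n$ — the literal $i/n$ grid is kept only for the
  equispaced kind — because unbounded families have infinite quantiles at
  $p = 1$.
* Sample-size inversion brackets by doubling and then bisects on the
  integer grid, regenerating the covariate at each candidate $n$; the
  returned $n$ is minimal (power at $n-1$ falls below the target).

## Problem sizes in the test suite

The suite checks the Monte-Carlo grids with 200 replicates per cell
(tolerance widened to five binomial standard errors accordingly); the
acceptance script reruns the headline cells at the full 1000 replicates.
Null calibration of $s_0$ uses 2000 replicates at $n = 100$ against a
Kolmogorov–Smirnov test at the 1% level; brute-force dense-matrix
equality is checked at $n \le 8$ to $10^{-10}$.

## Known limitations

* One changepoint only; no quadratic-segmented or harmonic bases.
* Families: gaussian-identity and binomial-logit.
* Analytic power covers the gaussian segmented model (the setting in
  which the alternative distribution is available in closed form), not
  the binomial family or the benchmark tests.
* Maximum-|t| critical values exist only for $10 \le n \le 50$; the
  trimmed LRT only at $\alpha = 0.05$.
* The changepoint-location estimate is a profile argmax with no
  uncertainty statement attached; use `fit_segmented` for standard
  errors in the broken-line case.
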