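---
title: "Methods: multi-intervention ITS for weekly prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-intervention ITS for weekly prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsprev)
```

## The estimand and the model

The pipeline estimates level shifts in a weekly prevalence series at known,
dated interruptions. The outcome is the survey-weighted share of respondents
reporting 15 or more mentally unhealthy days in the past 30 (a binarization
of the standard surveillance item that tracks clinically significant
anxiety/depression), expressed in percentage points. The working model is a
regression with ARIMA errors,

$$z_t = c\,t + \sum_{k} \omega_k I_k(t) + \eta_t,
\qquad \eta_t \sim \mathrm{ARIMA}(p, d, q),$$

where $I_k(t)$ is the binary indicator of interruption $k$ and $c$ is the
weekly trend. With $d = 1$ the trend term in levels is exactly the constant
(drift) of the differenced equation, so the reported `trend` coefficient is
the weekly drift in percentage points per week whichever $d$ is used. The
$\omega_k$ are static level shifts ("interventions" in the
quasi-experimental sense); no rational transfer-function dynamics are
modelled. Serial correlation is absorbed by the ARMA error, which is what
distinguishes the estimator from naive segmented OLS.

Assumptions worth stating plainly: the interruption dates are known and
exogenous; effects are step-shaped on the prevalence scale and begin a fixed
lag after the event; the error process is a non-seasonal, homoscedastic
ARIMA; and the weekly point estimates are treated as the series (their
sampling variance is not propagated, matching the practice the pipeline
replicates — denominators are retained for reporting only).

## The interruption design

The built-in calendar holds 11 events: 8 vaccine rollout phases and 3
pandemic-related events (January 2020 – June 2022). Two coding rules:

* **Lag.** Because the outcome item refers to the preceding 30 days, each
  indicator starts `lag_weeks = 4` whole weeks after the week containing the
  event date. Sensitivity lags (0, 2, 6) are a single argument away.
* **Persistence.** Rollout phases form one chronological sequence of
  mutually exclusive segments: each phase's indicator is 1 from its lagged
  onset until the next phase's lagged onset, the final phase running to the
  series end. All 8 phases are pooled into one sequence (booster and
  paediatric tracks are not separated — the replicated analysis chains them
  as a single progression). Pandemic events are coded as permanent steps,
  the conventional ITS encoding for a lasting shock; whether they should
  instead be bounded is genuinely undecidable, so `pandemic_coding` also
  offers `"pulse"` and `"segment"`.

Weeks follow the ISO-8601 convention (Monday start); the default grid is
2019-W01 through 2023-W08, 217 weeks. The source does not state its week
convention, so ISO weeks are a documented choice, as is mapping each
interview to the ISO week of its date.

## Estimation and diagnostics

`fit_its()` wraps `stats::arima` (Gaussian maximum likelihood; the default
`CSS-ML` uses conditional sums of squares only to initialise the exact ML
optimisation, `reltol = 1e-8`, up to 500 iterations) with the trend and
intervention columns as external regressors. Confidence intervals are
estimate ± 1.96 SE and p-values are 2-tailed normal, with no
multiple-testing correction across the 11 interventions — matching the
analysis being replicated. Two numerical choices deserve a note:

* **Degrees-of-freedom correction.** The ML innovation variance divides by
  $n_{\mathrm{eff}} = n - d$; with 13 estimated coefficients on 216
  effective observations that makes raw standard errors visibly optimistic
  (measured 93.2% coverage of nominal 95% intervals over 2000 simulated
  replicates). SEs are therefore inflated by
  $\sqrt{n_{\mathrm{eff}}/(n_{\mathrm{eff}}-k)}$, $k$ counting all ARMA and
  regression coefficients — the analogue of the $n-k$ divisor used by the
  t-based inference of classic ARIMA software. Measured coverage after the
  correction is 94.1% (type-I error ≈ 5.9%); the residual percentage point
  reflects MA-parameter uncertainty and is a known, documented limitation
  rather than something a further ad-hoc inflation should hide.
* **Degenerate exact fits.** When $p=q=d=0$ and the regression reproduces
  the series exactly, the ARMA likelihood is singular (zero innovation
  variance); the least-squares solution is the MLE there and is returned
  directly, with NA inference fields.

Diagnostics mirror the standard reporting set: BIC
($-2\log L + k\log n_{\mathrm{eff}}$, $k$ including the innovation
variance), the Ljung–Box portmanteau Q at `m = 18` lags (a common weekly
default; the source does not state `m`) with $\chi^2$ degrees of freedom
$m - (p+q)$ floored at 1, the Stationary $R^2$
$1 - \sum \hat e_t^2 / \sum (\Delta^d z_t - \overline{\Delta^d z})^2$ with
the mean of the differenced series as baseline (the exact baseline used by
the original software is undocumented; the mean baseline is implemented and
stated), and residual ACF/PACF with $\pm 1.96/\sqrt n$ bands.
`select_order()` fits a candidate grid and returns the minimum-BIC fit among
those with non-significant Ljung–Box (p > 0.05), falling back to minimum BIC
overall with a warning, ties broken toward smaller $p+q$. Missing weeks are
an error — silent interpolation would blur exactly the level shifts being
estimated.

## The LSTM distributional model

The companion forecaster is a stacked LSTM (default: 1 layer, 32 hidden
units) over sliding windows of `window = 12` weeks; each window carries the
prevalence value plus the 11 binary intervention indicators of those weeks,
and predicts the next week. The final hidden state feeds two parallel linear
heads: one for the predictive mean, one passed through
$\mathrm{softplus}(x) = \log(1 + e^x)$ (plus a $10^{-6}$ floor) for the
predictive variance. Training minimises the mean Gaussian negative
log-likelihood with Adam at learning rate 0.001 for 10 epochs. The network,
backpropagation through time and Adam are implemented in the package with
exact gradients (verified against central finite differences to $10^{-5}$).

Design choices the recipe leaves open, and how they were resolved:

* **Batch size 1.** An "epoch" is a complete seeded-shuffle pass over the
  training samples with per-sample updates. With full-batch updates, 10
  epochs would mean 10 Adam steps of size ~0.001 — no network trains under
  that budget, so per-sample updates are what make the stated
  10-epoch/lr-0.001 recipe meaningful. Configurable via `batch_size`.
* **Difference-parameterised mean head.** The mean head predicts the
  week-over-week change and the reported $\mu_t$ adds back the last
  observed value. Bounded tanh states cannot extrapolate a trending level
  (level-target training fails its own sanity checks on a noise-free
  trend); predicting changes is the sequence-model analogue of the $d = 1$
  differencing in the ARIMA stage. `predict_difference = FALSE` restores
  level targets.
* **Chronological 80/20 split and train-span standardization.** Random
  splitting would leak future information into training; the prevalence
  feature and targets are standardized by the mean/SD of the weeks available
  before the first test target, and predictions are de-standardized before
  reporting.

Per-epoch train/test MSE of the mean prediction (raw prevalence scale) and
the mean training NLL are recorded for epoch selection;
`predict_distribution()` returns $\mu_t$, $\sigma_t$ and the 95% interval
$\mu_t \pm 1.96\sigma_t$ for every predictable week.

One identifiability caveat: with inputs restricted to weeks
$i \dots i{+}w{-}1$ (the leakage-safe construction), the predicted week's
own indicator is never an input and, within a single realised series, the
indicators are collinear with the prevalence history — so a counterfactual
obtained by zeroing the intervention features is essentially undefined (its
contrast is numerically near zero with arbitrary sign). Intervention effects
in the LSTM stage are therefore read from the fitted mean around onsets
(post-onset vs pre-onset $\mu_t$), which recovers the sign of injected
steps reliably; attribution of magnitudes belongs to the ARIMA stage.

## The synthetic-data generator

`scenario()` encodes the data-generating process the estimator assumes:
217 ISO weeks from 2019-W01; baseline 12.9 pp (the pre-pandemic level);
drift 0.034 pp/week (the published trend constant); integrated MA(1) noise
with $\theta = 0.5$ and $\sigma_\varepsilon = 0.5$ pp (the main-model order
is 0,1,1; its MA point estimate is not usably printed, so $\theta = 0.5$ is
a one-time choice of a moderate smoothing coefficient, and
$\sigma_\varepsilon$ was set so that simulated weekly series show
week-to-week movements of the size visible in the published series);
step effects in percentage points on named events; `d = 0` plus `ar_phi`
for the stationary ARMA variants used at stratum scale and in closed-form
oracle tests. MA(1) noise is exact from the first observation; AR variants
use a 500-step burn-in. Everything is deterministic given the seed.

`simulate_microdata()` wraps a target weekly series back into
respondent-level records: per week a fixed number of respondents (default
150, a plumbing choice — the real weekly interview volume is not published),
log-normal weights ($\sigma_{\log} = 0.5$), days responses whose exceedance
probability equals the target prevalence (zero-inflated below the cutoff,
zero days recorded as code 88), special codes 77/99 at `missing_rate`, and
stratum labels from a share/shift mixture whose shifts are centred so the
weighted aggregate stays on target.

What the generator deliberately does **not** emulate: raking/weight
calibration (weights are consumed, never constructed), telephone-frame or
geographic structure, respondent-level covariance between weights and
outcomes, seasonality, and outcome-dependent nonresponse. Passing tests
therefore demonstrate that the estimator recovers what this generative
process encodes — correct lagged step effects under ARIMA noise and
weighted aggregation — not that the published real-data estimates are
correct, which would require the original microdata.

## Validation design and problem sizes

The test-suite validation has four tiers, with sizes chosen to keep the
whole suite a few minutes long while leaving Monte-Carlo error well below
the tolerances being checked:

* exact oracles — OLS equivalence of the (0,0,0) fit and brute-force
  recomputation of Q, BIC, Stationary $R^2$, ACF/PACF on 50 random small
  inputs, at $10^{-8}$;
* closed forms — ARMA moment formulas against 20 000-week simulations;
  softplus/NLL values and gradients at $10^{-5}$;
* calibration — 500-replicate recovery of each published effect size
  (unbiasedness within 3 MC SEs), 1000-replicate CI coverage (95% ± 2 pp)
  and type-I error (5% ± 2 pp) at the study's n = 217;
* LSTM sanity — beating the mean predictor on a noise-free trend and ≈95%
  interval coverage on 200 held-out points of a 1012-week stationary
  series (a length chosen to yield exactly 200 test windows).

## Known limitations

* Weekly prevalence sampling variance is not propagated into the ITS fit;
  strata with small denominators get noisy series without a warning beyond
  the reported `n_effective`.
* Nominal 95% CIs run ≈1 pp under after the df correction (MA-parameter
  uncertainty); bootstrap calibration would close this but is out of scope.
* The LSTM stage quantifies predictive uncertainty, not causal effects; see
  the identifiability caveat above.
* No seasonal ARIMA terms, GARCH errors, or state-space structural models;
  interruption dates are always user-specified, never detected.
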