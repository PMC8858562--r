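---
title: "A hierarchical time-series model for subnational sex ratios at birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical time-series model for subnational sex ratios at birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbtrans)
```

## The problem

Under natural conditions the sex ratio at birth (SRB, male births per
female birth) fluctuates within a narrow band around 1.03–1.07.  Where son
preference, accessible prenatal sex determination, and declining fertility
coincide, sex-selective abortion can push the SRB above that band — a
*sex-ratio transition* that rises, plateaus, and eventually returns to the
natural level.  At the subnational scale the evidence for such a transition
is thin: a handful of retrospective surveys and a census, with birth
samples small enough that sampling noise can mimic or mask genuine
inflation.  `srbtrans` estimates, for each province of a country, the
probability that such a transition is under way, reconstructs its
trajectory, and projects it forward probabilistically.

## The model

For province $p$ and year $t$ the SRB is

$$\Theta_{p,t} = b\,\Phi_{p,t} + \delta_p\,\alpha_{p,t},$$

with components:

* **Baseline** $b$ — the national SRB level, fixed at 1.049 and shared by
  all provinces.  It is treated as known: provincial birth samples are far
  too small to re-estimate it, and sampling it (like sampling the
  autoregressive parameters below) mostly inflates posterior uncertainty
  without adding information.
* **Natural fluctuation** $\Phi_{p,t}$ — a stationary first-order
  autoregressive process on the log scale:
  $\log\Phi_{p,1}\sim N(0, \sigma^2/(1-\rho^2))$ and
  $\log\Phi_{p,t}\mid\log\Phi_{p,t-1}\sim N(\rho\log\Phi_{p,t-1},
  \sigma^2)$.  Defaults $\rho = 0.9$, $\sigma = 0.004$ keep the
  fluctuation within roughly $\pm 2\%$ of the baseline, the order of
  magnitude of natural year-to-year SRB variation.
* **Inflation indicator** $\delta_p\in\{0,1\}$ — a spike-and-slab switch:
  $\delta_p \sim \mathrm{Bernoulli}(\pi_p)$ with a province-specific mean
  $\pi_p \sim U(0,1)$.  The posterior frequency of $\delta_p = 1$ is the
  province's *inflation probability*, the model's headline quantity.
* **Transition shape** $\alpha_{p,t}$ — a trapezoid: zero until the start
  year $\gamma_p$, linear increase over $\lambda_{1p}$ years to the
  maximum inflation $\xi_p$, a plateau of $\lambda_{2p}$ years, and a
  linear convergence back to zero over $\lambda_{3p}$ years.  Inflation is
  constrained non-negative: the model describes son-preference-driven
  imbalance and deliberately excludes SRB deflation.

Observed ratios $r_i$ enter through a lognormal likelihood,
$\log r_i \mid \Theta \sim N(\log\Theta_{p_i, t_i}, \sigma_i^2)$, where
$\sigma_i$ is the observation's pre-computed sampling error and $t_i$ the
midpoint year of its reference period (an option evaluates $\Theta$
averaged over the period instead; at these period lengths the difference
is negligible).  Precise observations therefore pull the fit harder than
noisy ones.

### Hierarchy and priors

The stage lengths and the maximum inflation follow truncated-normal
($\ge 0$) distributions across provinces.  Their means and standard
deviations are themselves given normal and half-normal hyperpriors.  The
defaults centre the total transition span at $13 + 10 + 13 = 36$ years and
the maximum inflation at $0.05$ — the scale of national transition
experiences observed in countries that have completed or nearly completed
a sex-ratio transition.  These are declared package defaults, exposed in
`model_config()`, not estimates.

The start year carries the *fertility squeeze*: sex selection becomes
attractive when families become small.  Its prior is a Student-t with 3
degrees of freedom centred on the first year the province's total
fertility rate (TFR) falls to or below a reference level $f^\*$ (default
3.0 children per woman, scale 10 years, start years restricted to
1970–2049).  The heavy tails deliberately allow provinces whose fertility
path is atypical to start early or late.  Because the location is resolved
from the TFR series supplied at fit time, a series extending through the
projection horizon lets future fertility decline inform future start
years; projection itself needs no further TFR input.

## Posterior computation

`fit_srb_mcmc()` uses Metropolis-within-Gibbs:

* single-site adaptive random-walk updates of each year's $\log\Phi$,
  vectorised across provinces, plus a whole-path preconditioned
  Crank–Nicolson move that leaves the Gaussian AR(1) prior invariant and
  moves the level of the path efficiently;
* adaptive random-walk updates of the shape parameters (several sweeps per
  iteration — they are cheap and mix slowest), and a joint
  independence refresh of all shapes from their conditional prior, which
  decorrelates the shapes instantly wherever $\delta_p = 0$;
* an exact two-point Gibbs step for $\delta_p$ using the likelihood with
  the trapezoid on versus off times the prior odds — no reversible jump is
  needed because the shape parameters are retained (and updated from their
  prior) while $\delta_p = 0$;
* a conjugate Beta step for $\pi_p$ and a near-conjugate proposal for the
  shape hyper-means (the truncation normaliser is the only correction, so
  acceptance is essentially 1).

Proposal scales adapt towards 44% acceptance during warmup and are frozen
afterwards.  All randomness flows from the single seed in `mcmc_config()`;
chains run sequentially on one RNG stream, so entire fits are exactly
reproducible.  Convergence is monitored by split-half R-hat and effective
sample size on a set of scalar summaries; a fit exceeding R-hat 1.05
completes with a prominent warning and is flagged, never silently
accepted.  Start-year summaries are reported conditional on
$\delta_p = 1$ (a start year is meaningless in draws without inflation),
as integer years with median ties broken to the earlier year.

## Projection

`project_srb()` extends every posterior draw: $\Phi$ by simulating the
AR(1) recursion forward, $\alpha$ by evaluating each draw's trapezoid
through the horizon.  Draws with future start years inflate in the future;
draws with $\delta_p = 0$ fluctuate around the baseline forever.  Because
every trapezoid has finite support, all median trajectories revert to $b$
at long horizons.  By default transitions may extend beyond the horizon
rather than being truncated at it; `transition_data_coverage()` reports
how much of each transition interval is actually overlapped by
observation periods — typically a small share, which is why the
hierarchical prior carries much of the projection.

## Data preprocessing

The survey-facing helpers mirror standard demographic practice for
full-birth-history data: annual counts are pooled into the shortest
periods whose delta-method coefficient of variation
$\sqrt{1/m + 1/f}$ stays below a threshold (default `cv_max = 0.1`,
keeping log-scale errors near or below 0.1); sampling errors are
delete-one-cluster jackknife estimates of the log ratio, reflecting the
multi-stage survey design; survey observations more than 25 years before
the interview are dropped to limit recall bias (censuses are exempt); and
census district counts are inverse-probability weighted by each district's
sampled fraction before provincial aggregation, with a delta-method error
attached to the weighted totals.

## The synthetic-data generator

`scenario_config()` / `simulate_srb_dataset()` generate ground truth and
observations with the statistical structure the model assumes: latent
$\Theta$ built exactly from the decomposition above, logistic declining
TFR curves, and clustered observations in which total births are split
multinomially across equal-expectation clusters and male counts are
binomial with $p = \Theta/(1+\Theta)$ — so the reported jackknife errors
are *real* design-based errors, not plugged-in constants.  The defaults
emulate a seven-province, four-survey-plus-census setting: about 5,000
births per survey observation over 40 clusters, three five-year periods
per survey, fertility falling from about 6 to about 2 children per woman,
and transitions starting around the turn of the millennium in four of the
seven provinces.

What the generator does *not* emulate: stratification and non-response,
recall error (beyond what the recall filter would remove), heaping of
reported birth years, and covariance between observations from the same
survey.  Passing recovery tests therefore demonstrate that the inference
machinery is correct and calibrated *under the model's own assumptions*;
they cannot certify robustness to the measurement pathologies of real
birth-history data.

## Validation machinery

`holdout_split()` implements a deterministic, collection-time split:
observations from surveys fielded in or after a cutoff (default 2016)
form the test set — retrospective data arrive in series, so holding out
whole late surveys tests genuine predictive power where a random split
would leak information.  Held-out ratios are scored against the posterior
of $\log\Theta$ at their midpoint year convolved with their own
observation noise.  `simulation_study()` runs simulate–fit–score
replicates; with `randomize_shapes = TRUE` the true shapes are drawn from
the model prior, making 95% credible-interval coverage a proper Bayesian
calibration check (hyper-mean uncertainty is not re-drawn per replicate,
which if anything makes the check conservative).  Replicates failing the
convergence check are excluded and counted, never averaged in silently.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a merge block that cannot reach
the CV threshold is emitted with a warning; a jackknife replicate with
zero births of either sex is an error naming the cluster; a TFR series
never crossing $f^\*$ locates the start-year prior at its last year with
a warning; a province with no $\delta = 1$ draws returns an explicitly
flagged undefined start year.  Ties in integer-year medians and in
argmax-over-years break to the earlier year throughout.

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every stage in minutes on a single core: fits of 2 chains with
1,000-iteration warmup and 2,000 retained iterations for headline
quantities, and recovery studies of 10–20 replicates at 7 provinces with
2,000 stored draws each (4,000 iterations thinned by 2).  These sizes give
Monte-Carlo error comfortably inside the tolerances being checked;
production analyses should scale the chain settings up, and the
diagnostics will flag when they are too small.

## Known limitations

* The fertility squeeze is the only covariate: son-preference intensity,
  conditional SRB by birth order, and similar signals are not modelled.
* Inflation is non-negative by assumption; girl-preference deflation is
  out of scope.
* The AR(1) constants and baseline are fixed from national-level
  information rather than estimated, a deliberate bias–variance trade.
* With few observations per province, the posterior for the later
  transition stages is prior-driven; the data-coverage diagnostic makes
  this visible but does not remove it.
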