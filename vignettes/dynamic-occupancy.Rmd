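---
title: "Dynamic occupancy modeling of camera-trap surveys with dynoccam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic occupancy modeling of camera-trap surveys with dynoccam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynoccam)
```

## The model

`dynoccam` analyses multi-season camera-trap surveys in which sites are
visited by a species that may colonize or abandon them between seasons,
and is detected imperfectly within seasons. The data are detection
histories $y_{itj} \in \{0, 1, \mathrm{NA}\}$ over sites $i$, primary
periods (seasons) $t = 1, \dots, T$, and secondary occasions $j$ (weeks
of camera operation). Four linked submodels are estimated on the logit
scale:

* **initial occupancy** $\psi_{1,i}$ — intercept, moth-damage severity,
  percent cover, road distance;
* **colonization** $\gamma_{i,t}$ and **extirpation** $\epsilon_{i,t}$ —
  the ten-term structure
  $\beta_0 + \beta_1\,\mathrm{precip}_{t} + \beta_2\,\mathrm{season}_t +
  \beta_3\,\mathrm{precip}_{t}\mathrm{season}_t + \beta_4\,\mathrm{zone}_i +
  \beta_5\,\mathrm{cover}_i + \beta_6\,\mathrm{zone}_i\mathrm{cover}_i +
  \beta_7\,\mathrm{moth}_i + \beta_8\,\mathrm{TSD}_t +
  \beta_9\,\mathrm{moth}_i\mathrm{TSD}_t$;
* **detection** $p_i$ — intercept, cover, zone area, plus a site-level
  random intercept $\eta_i \sim \mathrm{N}(0, \sigma_\eta^2)$ absorbing
  unmodeled detection heterogeneity.

Transitions are dummy coded by the season they leave: summer-to-winter
(autumn) is 0 and winter-to-summer (spring) is 1, so positive season
effects mean higher rates in spring. The precipitation and
time-since-disturbance values attached to transition $t \to t+1$ are
those of the origin period $t$: autumn transitions carry the preceding
summer's rain, spring transitions the preceding winter's snow.
Continuous covariates are mean-centered and scaled by the sample
standard deviation (n − 1), so coefficients are comparable as effects
per covariate standard deviation; the fit-time means and scales are
stored and replayed verbatim when transforming prediction grids. The
ordinal moth score (0–4) is treated as a standardized numeric severity
by default (`standardize_moth = FALSE` keeps the raw score), which is
what its product interaction with TSD requires.

### Marginalized likelihood

The latent occupancy chain $z_{it}$ is a two-state hidden Markov chain
with initial law $(1-\psi_{1,i}, \psi_{1,i})$ and transition rows
$(1-\gamma, \gamma)$ and $(\epsilon, 1-\epsilon)$. Rather than sampling
$z$, the package marginalizes it with the forward algorithm: period
emissions are $\prod_j p^{y}(1-p)^{1-y}$ over surveyed occasions when
occupied, the indicator of no detection when unoccupied, and 1 for
fully missing periods. Sites first deployed in later seasons still
start their chain at period 1 — their early periods are all-missing
emissions, so $\psi_1$ refers to the first study season for every site.
Marginalization keeps the posterior continuous (valid for
gradient-based samplers) and makes the likelihood exactly testable
against brute-force enumeration over all $2^T$ latent sequences, which
the test suite does on hundreds of random instances at $T \le 4$.

### Priors and sampling

The survey's published protocol does not state prior families, so the
package uses weakly informative defaults on the standardized scale —
normal(0, 2.5) on all coefficients, half-normal(0, 1) on
$\sigma_\eta$ — with every scale exposed in the run configuration. The
random effect is non-centered ($\eta_i = \sigma_\eta \tilde\eta_i$,
$\tilde\eta_i \sim \mathrm{N}(0,1)$), which removes the funnel that
otherwise appears when the data carry little information about
$\sigma_\eta$.

Sampling is Hamiltonian Monte Carlo written against the analytic
gradient of the marginalized log-posterior (the gradient is computed by
scaled forward–backward recursions in compiled code and verified
against finite differences). Warmup adapts the step size by dual
averaging toward 80% acceptance and estimates a diagonal metric from
the middle of warmup; trajectory lengths are jittered uniformly up to
`L_max` (default 25) to avoid resonance. Three chains with random
starting values are the default, with 2500 warmup and 5000 kept
iterations per chain mirroring the field protocol; the scaled-down
test configurations (3 × (500 + 1000)) converge with split R-hat below
1.05 on the survey-sized synthetic datasets. Draws are
seed-deterministic: chain $c$ uses seed `seed + 1000(c-1)`.

Convergence is graded with the split-chain rank-normalized potential
scale reduction factor, and inference follows the posterior median with
`p_pos`, the pooled fraction of draws above zero. Support is strong at
`p_pos` ≥ 0.90 or ≤ 0.10 and moderate between 0.70/0.30 and the strong
bounds; the strong label takes precedence on the shared boundary, and
the comparison is arranged as $1 - p_\mathrm{pos} \ge$ threshold so the
0.10 boundary is exact in floating point. Medians beyond ±1 are flagged
as large effects.

## Detection processing

Photos of the same species at the same site (both paired cameras
pooled — the pair exists to maximize detection, not to duplicate
effort) are clustered greedily left to right: a photo is an independent
detection if at least 20 minutes have elapsed since the last *kept*
photo, so the boundary case is kept and the filter is idempotent.
Deployment windows are tiled into 7-day occasions from the window
start; a trailing partial occasion shorter than half a week is dropped,
otherwise kept. Weekly occasions are a package choice: the field
protocol states only a 12-week minimum season, and weekly tiling
reproduces at least 12 occasions under it. Trap-night accounting
defaults to camera-nights (two cameras per site) with a site-night
switch in the configuration.

## What the synthetic generator emulates — and what it does not

`scenario()` draws landscapes whose supports mirror the study region:
log-normal road-bounded zone areas (km²), beta-distributed percent
cover, exponential road distances, a categorical 0–4 moth-damage
severity, and seasonal precipitation totals in inches with winter snow
exceeding summer rain on average. The latent dynamics run the exact
generative counterpart of the fitted model, and detected occasions can
be expanded into clustered photo bursts (1 + Poisson extra photos,
exponential gaps capped well inside the 20-minute window, occasional
independent revisits) so the whole pipeline from raw photos onward is
exercised. `scenario_published()` reproduces the published survey
schedule (100 → 200 → 240 → 100 sites over eight seasons) with the
published bobcat posterior medians as true coefficients where printed;
intercepts and unprinted coefficients are synthetic defaults chosen to
keep baseline rates moderate, so that scenario supports qualitative,
not numeric, comparison.

The generator does not emulate spatial autocorrelation between sites,
animal movement, camera failure part-way through a season, or
species misidentification. Passing recovery tests therefore show that
the estimator is correct and calibrated *for data meeting the model's
assumptions*; they cannot certify robustness to violations real
surveys may exhibit.

### The recovery scenario

Calibration experiments use `scenario_recovery()`: 120 sites, 8
periods, 12 weekly occasions, all coefficient magnitudes at or below
1.6 and $\sigma_\eta = 0.5$. It differs from the study-emulating
default in one respect: precipitation is drawn from the same
distribution in both seasons. Realistic totals differ systematically
between snow and rain, which makes the pooled-standardized
precipitation column nearly collinear with the season dummy across
only seven transitions; a calibration run that wants to attribute bias
to the *estimator* needs those two columns identified separately, so
the recovery design balances them — the usual orthogonal-design choice
for simulation studies. Under this scenario, 20-replicate experiments
give pooled 90%-interval coverage near nominal and standardized z
scores of the posterior medians with mean ≈ 0 and spread ≈ 1.
Coefficients informed only by the seven period-level values
(precipitation and TSD main effects and their interactions) remain the
widest; their posterior spread is a property of an eight-season design,
not of the sampler.

## Derived dynamics and prediction

From each posterior draw the package projects
$\psi_{t+1} = \psi_t(1-\epsilon_t) + (1-\psi_t)\gamma_t$, turnover
$\tau_t' = \psi_t\epsilon_t + (1-\psi_t)\gamma_t$, the per-season rate
of change $\lambda = \psi_\mathrm{last}/\psi_\mathrm{first}$ (first
versus last year of each season class), and the stable state
$\psi^\mathrm{eq} = \gamma/(\gamma+\epsilon)$, the fixed point of the
projection. All derived quantities are computed draw-wise and then
summarized — medians of nonlinear functionals are not functionals of
the medians, and the draw-wise path is the contract the tests pin
down. Decline proportions $c_s$ and $c_w$ (the share of cells with
$\lambda < 1$, strict) are reported from the cellwise posterior-median
$\lambda$, with a draw-wise posterior of the proportion alongside.

Grid prediction removes cells with more than 40% high-development
cover or open water *before* any proportion is computed, transforms
the remaining covariates through the stored standardization, and flags
covariates far outside the fitted range as extrapolation rather than
failing. For the seasonal stable states the choice of covariate
settings is genuinely open (the source protocol is silent); the
package fixes the transition class to the season's entering transition
(spring for summer, autumn for winter) and averages $\gamma$ and
$\epsilon$ draw-wise over that season's transitions before forming
$\gamma/(\gamma+\epsilon)$. "Over the course of the study" for
$c_s/c_w$ is read as first-year-versus-last-year within each season
class; per-transition $\lambda$ values are also emitted.

## Numerical choices and degenerate inputs

* Forward recursions are scaled per period; a history impossible under
  the parameters returns $-\infty$, never an exception, and the
  sampler treats it as a rejection.
* `standardize()` refuses zero-variance covariates; period covariates
  fall back to the full period sequence when fewer than two distinct
  transition values exist (T = 2 designs).
* $\lambda$ is undefined (flagged `NA`) at $\psi_\mathrm{first} = 0$;
  $\psi^\mathrm{eq}$ at $\gamma = \epsilon = 0$; periods with no
  surveyed site yield `NA` naive occupancy with a warning.
* Timestamps are parsed as naive local time in one study time zone;
  DST is ignored, which cannot change 20-minute gaps materially.
* Overlapping deployment windows for one site and period are merged to
  their union before occasions are tiled.

## Problem sizes used by the checks

The packaged checks run likelihood-oracle comparisons at $T \le 4$,
$J \le 3$ (hundreds of instances in seconds), single fits and
20-replicate recovery experiments at 120 sites × 8 periods × 12
occasions with 3 chains × (500 + 1000) iterations (roughly 20 seconds
per fit with the compiled gradient), and an end-to-end bobcat-like run
over the published survey schedule. These sizes were chosen so a full
check cycle completes in minutes on a single core while leaving the
survey-scale structure (staggered deployments, seasonal alternation,
random-effect heterogeneity) intact.

## Known limitations

* Detection is occasion-constant per site (plus the random effect);
  occasion-varying detection covariates would require extending the
  sufficient-statistic fast path (the R reference `site_loglik()`
  already accepts per-occasion `p`).
* Precipitation is one value per period; the table schema would admit
  site-varying precipitation, but the design builder currently
  replicates the period value across sites.
* No model selection, spatial autocorrelation, or multi-species joint
  structure — single-species fits mirror the source workflow.
* Eight seasons identify period-level effects weakly; users should
  read wide intervals on precipitation/TSD terms as a design property.
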