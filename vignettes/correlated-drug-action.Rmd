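---
title: "Correlated drug action: models, fitting choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated drug action: models, fitting choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdaction)
```

## The model

Independent drug action states that a unit (patient or cell) exposed to
two drugs experiences the outcome of whichever drug serves it best. The
correlated extension keeps that mechanism but lets the two latent
single-drug outcomes be rank-correlated with Spearman correlation
$\rho \in [-1, 1]$, the model's only fitted parameter.

**Temporal (tCDA).** Latent survival times $t_A, t_B$ give
$t_{AB} = \max(t_A, t_B)$. Assuming the joint distribution is a mixture
in which a fraction $\alpha = |\rho|$ of units sits on the
matched-quantile curve $S_B^{-1}(S_A(t_A))$ (or its anti-matched mirror
for $\rho < 0$) while the rest pair independently, the combination
survival has the closed form implemented in `tcda_survival()`; the
mixture makes $\alpha(\rho) = |\rho|$ exact rather than an approximation.
Under that distribution, fitting recovers the generating correlation
essentially perfectly; the window-swap construction (below) generates a
*different* joint distribution with the same marginals and target
correlation, and recovery remains almost as good — the basis for treating
the fitted $\rho$ as robust to the unknown true joint law.

**Dose-space (dCDA).** Latent lethal doses $\delta_A, \delta_B$; a cell
survives iff both exceed the applied doses. Correlation additionally
*enhances* doses: at $\rho = 1$ the partner drug's dose converts through
the equivalent-dose maps $f, g$ (matched Hill quantiles), which is what
makes the $\rho = 1$ limit sham-compliant (Loewe-consistent) rather than
plain highest-single-agent. At $\rho \le 0$ no enhancement applies; the
$\rho = -1$ limit is the Fréchet bound. `dcda_viability()` implements the
$|\rho|$-weighted mixture of these limits with Bliss independence.

The enhancement weights between the endpoints are not identifiable from
first principles; this package (like the closed form it implements)
applies full enhancement within the correlated component only. The
synthetic generator uses the same convention, which is why cell counting
and closed form agree to sampling error (`test-acceptance.R` checks
sup-norm 0.03 at $N = 10^4$ for curves, 0.02 at $N = 10^5$ for
matrices).

## Parameters that matter

* `rho` — Spearman correlation of latent outcomes; fitted over a 200-point
  grid on $[-1, 1]$ (`grid_size`). RMSE ties break toward the smallest
  $|\rho|$: when two candidates explain the data equally well, the less
  structured explanation is preferred.
* `dt = 0.05` months — the regular time grid onto which survival curves
  are linearly interpolated before fitting; arms are truncated to their
  common span so that missing late-time data cannot bias the RMSE.
* `n_boot = 5000` — bootstrap replicates; each replicate resamples every
  arm by inverse transform with that arm's *cohort size*, so the interval
  reflects the trial's actual information content.
* Hill parameters `k` (EC50, drug units) and `n` (steepness),
  per monotherapy.
* Significance levels: a screen-wide corrected threshold
  $\alpha / m$ (default $\alpha = 0.05$) for the goodness-of-fit
  decision across $m$ combinations; a fixed 0.01 for Excess-over-Bliss
  validity and for local per-dose flags, matching the conventions the
  screen analysis was designed with.

## Numerical and design choices

**Monotonization.** Digitized survival curves may locally increase by a
few hundredths. Input is monotonized by running minimum and rejected only
when a point exceeds the running minimum by more than 0.02 — accepted
noise for plot digitization, an error for anything larger.

**Inverse-transform sampling.** Survival times are drawn through the step
inverse of $1 - S(t)$ on the grid; draws beyond the observed event
fraction park at the last grid time. Empirical curves rebuilt from such
samples treat the mass exactly at the last grid time as censored (alive
through it); without this convention the final grid point of every
simulated curve would be biased low by the whole censored fraction.

**Coin pairing.** Starting from rank-matched sorted vectors, each index
*stays* matched with probability $|\rho|$; the complementary set is
permuted en bloc; negative targets reverse the result. (Swapping with
probability $|\rho|$ instead would destroy the $\rho = 1$ limit; staying
is the reading consistent with the mixture the closed form is derived
from.) The expected fraction remaining on the matched curve equals
$|\rho|$, so the achieved Spearman correlation is unbiased.

**Window swap.** Sweeps of local swaps inside a window of half-width `w`
(start $N/10$), with `w` doubled while the correlation is still above
target and the sweep rolled back and `w` halved on overshoot, until the
achieved correlation is within `tol` (default 0.01, the stopping rule the
construction was described with). A `"step"` adaptation ($w \pm 1$) is
available. Non-convergence after `max_iter` sweeps raises an error
carrying the best-achieved value.

**Hill fitting.** The screen-analysis recipe — interpolate viabilities
densely, fit one least-squares line, read the EC50 from
$k = (50 - i)/s$, then scan the steepness $n$ for lowest RMSE — is kept
as the initialization, with two amendments chosen deliberately:

1. the line is fitted inside the 40–60% viability band (full range only
   as a fallback). A single line through a sigmoid sampled over its full
   range carries a steepness-dependent EC50 bias of 15–30% on log-spaced
   dose designs;
2. `(k, n)` are then jointly polished on a local RMSE grid
   (`refine = TRUE`). The residual few-percent EC50 bias of any
   one-line estimate translates into correlation errors larger than the
   model's entire $\rho$ sensitivity — with the bare two-stage estimate
   the fitted correlation pins to $+1$ for generating values as low as
   0.3, and no recovery criterion can be met. `refine = FALSE` reproduces
   the bare recipe exactly (its EC50 is also always available as the
   `"k_linear"` attribute).

**Outliers.** Observed is regressed on predicted; externally studentized
residuals are compared with the two-sided Bonferroni cutoff
$t_{1 - 0.05/(2n),\, n-3}$. The final $\rho$ is refitted without flagged
cells; statistics report the non-outlier cells.

**Local flags.** Gated on the global paired-t goodness of fit passing at
0.01 (a locally deviant cell inside a globally misfitting combination is
not interpretable). Residual mean and variance use the normal MLE
($1/n$); each cell is held out, $\rho$ refitted, and the held-out
residual converted to a two-sided normal p-value; flagged cells are
labeled synergistic or antagonistic by the sign of their Excess-over-CDA.

**Degenerate inputs.** Flat survival at 1 (no events) cannot be sampled;
single-point curves cannot be regridded; constant predictors have no
studentized residuals; zero-variance non-zero differences have no t
statistic — each raises an informative error rather than a silent NA.
A perfect fit (zero residual variance) short-circuits local flags to
"all consistent".

## What the synthetic generators emulate — and what they do not

`gen_trialset()` builds monotherapy arms as Hill-shaped survival curves
(time in months playing the role of dose) and a combination arm from
$N$ simulated patients paired at the target correlation;
`gen_combination_matrix()` counts surviving cells on a 6 × 6 log-spaced
dose grid spanning two octaves either side of each EC50 (the default
screen design), adds Gaussian viability noise (default 0.02, typical
plate-reader replicate scatter after normalization), and clips to
$[0, 1.5]$ as normalized luminescence can exceed 1.

Defaults are fixed study conditions, not tuning knobs: Hill marginals
$(k = 1, n = 2)$ and $(k = 2, n = 1.5)$, $10^4$ cells or 4000 patients,
noise 0.02. Real data differ in ways the generators deliberately omit:
survival curves carry digitization error, informative censoring, and
cohort attrition rather than clean multinomial sampling; viability
screens have plate effects, edge effects, and dose-dependent error;
monotherapy responses need not be Hill-shaped at all. Passing recovery
tests therefore demonstrates the estimator's correctness under the
model's own assumptions, not robustness to assay artifacts.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 400–4000
patients per arm, $10^4$–$10^5$ cells per matrix, 300–1000 bootstrap
replicates (default 5000 for analyses), a 13-point correlation sweep for
the recovery $R^2$, and 50 repetitions for the bootstrap coverage study —
sizes at which the checked tolerances are comfortably inside sampling
error while a full run stays interactive.

## Known limitations

* Two drugs only; published multi-drug arms can be treated as one
  pseudo-monotherapy arm, but no recursive composition is provided.
* $\alpha(\rho) = |\rho|$ is fixed; no alternative interpolation
  families, and no time- or dose-varying correlation.
* The Kolmogorov–Smirnov goodness of fit compares deterministic quantile
  samples of the two curves (size = combination cohort); it is a
  repeatable summary of curve separation, not an exact sampling-theory
  test under censoring.
* The paired-t tests treat matrix cells as exchangeable replicates,
  ignoring spatial/dose structure in the residuals.
* Negative correlations shrink the identifiable signal when the dose
  grid rarely reaches $V_A + V_B < 1$; confidence intervals there are
  wide.
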