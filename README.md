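# cdaction

Correlated drug action (CDA) models for two-drug combinations, in time and
in dose space.

## The problem

Many clinical drug combinations work not because the drugs interact, but
because each patient benefits from whichever drug happens to work best for
them — *independent drug action*. The same logic applies to cells in a
culture exposed to two compounds. Before declaring a combination
synergistic, one should ask whether this null model, allowing for
correlation between the two single-drug responses, already explains the
data.

`cdaction` implements that null model with a single interpretable
parameter: the Spearman correlation ρ between the latent per-unit
outcomes under the two monotherapies.

**Temporal model (tCDA).** Each patient has latent survival times t_A,
t_B under the two monotherapies and survives t_AB = max(t_A, t_B) under
the combination. With S_max(t) = max(S_A, S_B), S_min = min(S_A, S_B) and
α = |ρ|:

    S_AB(t) = S_max + S_min (1 − S_max)(1 − α)                       ρ ≥ 0
    S_AB(t) = (S_A + S_B − S_A S_B)(1 − α) + min(1, S_A + S_B) α     ρ < 0

ρ = 0 is the Bliss-form independence limit, ρ = 1 the best single agent,
ρ = −1 the anti-correlated bound.

**Dose-space model (dCDA).** Each cell has latent lethal doses δ_A, δ_B;
it survives a dose pair iff both lethal doses exceed the (enhanced)
applied doses. With Hill monotherapy curves V_X(D) = 1 / (1 + (D/k_X)^n_X)
and equivalent-dose maps f(D_A) = k_B (D_A/k_A)^(n_A/n_B),
g(D_B) = k_A (D_B/k_B)^(n_B/n_A):

    V_AB = (1 − α) V_A V_B + α min{V_A(D_A + g(D_B)), V_B(D_B + f(D_A))}   ρ ≥ 0
    V_AB = (1 − α) V_A V_B + α max(0, V_A + V_B − 1)                       ρ < 0

This interpolates Bliss independence (ρ = 0), a sham-compliant
highest-single-agent model (ρ = 1; a drug "combined" with itself obeys
V_AB = V_A(D_A + D_B), i.e. Loewe additivity), and the Fréchet lower
bound (ρ = −1).

ρ is fitted by a 200-point grid search minimizing the RMSE between
prediction and observation. Around the fit the package provides bootstrap
confidence intervals, Kolmogorov–Smirnov and paired-t goodness of fit,
outlier-robust refitting via externally studentized residuals,
Excess-over-Bliss validity testing, the Excess-over-CDA synergy map,
leave-one-out local synergy/antagonism flags, rank-correlation-constrained
joint simulators (coin and window-swap pairing), and synthetic-data
generators with known ground truth.

## Worked example

Simulate a 400-patient-per-arm trial whose true correlation is 0.4, fit
the temporal model and bootstrap the confidence interval:

```r
library(cdaction)
spec <- synth_spec(hill_A = hill_params(10, 2, "drug A"),
                   hill_B = hill_params(14, 1.6, "drug B"),
                   rho_true = 0.4, n_units = 400,
                   time_grid = seq(0, 60, by = 0.05), seed = 20)
trial <- gen_trialset(spec)
fit <- fit_tcda(trial)
fit$ci <- bootstrap_rho_ci(trial, n_boot = 1000, seed = 21)
print(fit)
#> tCDA fit synthetic rho=0.4
#>   rho_hat = 0.3869  (alpha = |rho| = 0.3869 )
#>   RMSE = 0.009447  over 1201 grid points (dt = 0.05 months)
#>   95% bootstrap CI: [ 0.0651 , 0.759 ]
#>   KS goodness-of-fit p = 1
```

The fitted correlation (0.39) recovers the generating value within the
grid resolution plus sampling error of a 400-patient cohort; the KS test
finds no evidence against the model, so the combination's benefit here is
fully explained by correlated independent action — no synergy needed.

The dose-space pipeline on a simulated 6 × 6 viability screen (10,000
cells, measurement noise 0.02, true ρ = 0.3):

```r
mspec <- synth_spec(rho_true = 0.3, n_units = 1e4, noise_sd = 0.02, seed = 22)
dfit <- fit_dcda_pipeline(gen_combination_matrix(mspec))
print(dfit)
#> dCDA fit synthetic rho=0.3
#>   rho_hat = 0.2864 (initial 0.2864 ); RMSE = 0.01537
#>   Hill A: k = 0.9993 n = 2.04 | Hill B: k = 1.963 n = 1.46
#>   outliers removed: 0 | GoF paired-t p = 0.933 | EOB validity p = 0.00214
#>   local non-dCDA cells: 0
```

The Hill parameters (true: k = 1, n = 2 and k = 2, n = 1.5) and the
correlation are recovered; the paired-t goodness of fit keeps the dCDA
null, while the Excess-over-Bliss validity test (p = 0.002 < 0.01)
correctly warns that plain Bliss would *not* be an adequate null for this
correlated combination. `dfit$eocda` holds the per-dose synergy map.

Real data enter through `read_survival_table()` (CSV columns
`time_months,survival`, cohort size supplied per arm) and
`read_dose_matrix()` (dose-grid header and first column, optional dose-0
monotherapy row/column). `run_batch()` fits a manifest of combinations
and applies the screen-wide corrected threshold α/m. A thin command-line
wrapper lives at `inst/cli/cda.R`.

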