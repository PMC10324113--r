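# tacropk

Steady-state population pharmacokinetics of oral tacrolimus (TAC) in mice,
with treatment-group covariates on apparent clearance — the analysis used to
quantify how gut-microbiome depletion changes TAC whole-blood exposure and
its between-animal variability.

The package is aimed at pharmacometricians and quantitative biologists who
want a self-contained, fully testable reimplementation of that analysis:
a one-compartment oral model at steady state, log-normal between-subject
variability fitted by SAEM, empirical-Bayes conditional modes with derived
AUC₀₋₂₄ and half-life, the downstream variance-equality / covariate /
correlation statistics, and a synthetic-study generator with known truth
(the raw animal data are not publicly deposited).

## Model

Whole-blood concentration at steady state under repeated oral dosing
(dose *D* every τ = 24 h), for one compartment with first-order absorption
and elimination (*Ke = CL/V*):

```
C_ss(t) = D·Ka / (V·(Ka−Ke)) · [ e^{−Ke·t}/(1−e^{−Ke·τ}) − e^{−Ka·t}/(1−e^{−Ka·τ}) ]
```

Individual parameters are log-normal around group-specific typical values,
with the treatment group acting additively on log-CL:

```
CL_i = CL_pop·exp(β_g + η_i1),  V_i = V_pop·exp(η_i2),  Ka_i = Ka_pop·exp(η_i3),
η_i ~ N₃(0, Ω)
```

Derived exposures: `AUC₀₋₂₄ = D/CL_i`, `T½ = ln2·V_i/CL_i`. Estimation is by
SAEM (MCMC E-step, closed-form M-step), marginal likelihood by per-subject
importance sampling, standard errors by Louis' identity. Observations below
the 0.5 ng/mL quantification limit are handled by a censored likelihood
(M3) by default. See `vignettes/tacropk-methods.Rmd` for the full account.

## Worked example

Simulate a study at the default design (99 mice, four arms, ~3.5 sparse
samples each, LLOQ censoring) with truth anchored to the published
estimates, fit it, and derive the group exposures:

```r
library(tacropk)

sim <- simulate_study(default_paper_design(), default_truth(), seed = 1)
fit <- fit_saem(sim$data, pk_model_spec(), saem_config(seed = 1))
fit
#> SAEM population PK fit
#>   99 subjects, 350 observations (0 BLQ excluded), additive error
#>         parameter estimate      se   ci_lo   ci_hi
#>            cl_pop   0.3296 0.01801  0.2962  0.3669
#>             v_pop   1.8168 0.06794  1.6884  1.9549
#>            ka_pop   1.2196 0.06505  1.0986  1.3540
#>      beta_TAC+ATB   0.3203 0.08854  0.1468  0.4939
#>      beta_TAC+ZSQ  -0.5860 0.08916 -0.7607 -0.4112
#>  beta_TAC+ATB+ZSQ  -1.1696 0.08304 -1.3323 -1.0068
#>   omega SDs: 0.273 0.297 0.195
#>   error: a = 2.35, b = 0 | loglik = -1008.48 (MC se 0.277), AIC = 2043.0, BIC = 2093.1
#>   converged: TRUE | MH acceptance: 0.29 0.29 0.28 | SEs: louis
```

The simulation truth was CL/F = 0.32 L/h, V = 1.88 L, Ka = 1.20 1/h with
β = (+0.399, −0.594, −1.151) on log-CL: every fixed effect is recovered
within its 95% CI. Individual empirical-Bayes estimates and group AUC
summaries:

```r
ebe <- ebe_estimates(fit, sim$data, refine_mcmc = FALSE, seed = 1)
group_auc_summary(ebe, groups = sim$data$groups)
#>         group  n  mean variance ci_lo ci_hi
#> 1         TAC 36 232.1     3243 212.8 251.3
#> 2     TAC+ATB 21 177.5     1577 159.4 195.6
#> 3     TAC+ZSQ 21 432.2    12864 380.5 483.8
#> 4 TAC+ATB+ZSQ 21 756.0    60244 644.3 867.7

brown_forsythe(split(ebe$auc, ebe$group))
#> brown_forsythe: statistic = 17.57, df = (3, 95), p = 3.748e-09
```

The simulated study reproduces the reported structure: antibiotic-treated
mice have the lowest exposure, efflux inhibition raises it, and the AUC
variance grows with the mean across arms (highly significant
Brown–Forsythe test, mirroring the published variance gradient). The
published group contrasts themselves are exact arithmetic on the printed
means:

```r
percent_change(195.4, 131.1)   # -32.9  -> the reported "33% reduction"
percent_change(353.8, 617.5)   # +74.5  -> the reported "75% increase"
half_life(pk_params(0.32, 1.88, 1.20))  # 4.07 h vs the printed 4.08
```

A command-line pipeline covering simulate → fit → ebe → derive →
variance-test → report is exposed through `pk_cli()`:

```r
pk_cli(c("simulate", "--seed", "1", "--out-dir", "out"))
pk_cli(c("fit", "--seed", "1", "--out-dir", "out"))
pk_cli(c("ebe", "--seed", "1", "--out-dir", "out"))
pk_cli(c("variance-test", "--out-dir", "out"))
pk_cli(c("report", "--out-dir", "out"))
```

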