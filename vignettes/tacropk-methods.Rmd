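---
title: "Methods: steady-state population PK of oral tacrolimus in mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state population PK of oral tacrolimus in mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tacrolimus (TAC) is a narrow-therapeutic-index immunosuppressant whose
whole-blood exposure varies widely between and within individuals. In mouse
experiments probing the gut microbiome's contribution to that variability,
exposure is summarised by the area under the steady-state concentration-time
curve over one dosing interval (AUC~0-24~), estimated from sparse whole-blood
sampling (a handful of time points per animal) through a population
pharmacokinetic model. `tacropk` implements that analysis end to end:
the structural model, the nonlinear mixed-effects layer, SAEM estimation,
empirical-Bayes individual estimates, the downstream group comparisons, and
a synthetic-study generator so that every stage is testable without access
to the raw animal data (which are not publicly deposited).

## Structural model

A one-compartment model with first-order absorption and elimination. With
apparent clearance $CL/F$ (L/h), apparent volume $V/F$ (L), absorption rate
$K_a$ (1/h) and $K_e = CL/V$, the steady-state concentration at time $t$
since the last of many doses $D$ given every $\tau$ hours is

$$C_{ss}(t) = \frac{D K_a}{V (K_a - K_e)} \left[
  \frac{e^{-K_e t}}{1 - e^{-K_e \tau}} -
  \frac{e^{-K_a t}}{1 - e^{-K_a \tau}} \right].$$

Derived quantities: $T_{1/2} = \ln 2 \, V / CL$,
$\mathrm{AUC}_{0-\tau} = D / CL$, and the single-dose peak time
$T_{max} = \ln(K_a/K_e)/(K_a - K_e)$.

Numerical choices:

* **Units.** Dose in ng, volume in L; all internal arithmetic is in ng/L,
  converted to ng/mL exactly once at the public boundary. One conversion
  point means one place to audit.
* **$K_a \to K_e$ degeneracy.** The closed form cancels catastrophically
  when $K_a \approx K_e$; below $|K_a - K_e| < 10^{-8} K_e$ the analytic
  limit $C(t) \propto t e^{-K_e t}$ (and its steady-state analogue) is
  used. Continuity across the switch is property-tested.
* **Steady state, not superposition.** Dosing for 5 days at $\tau$ = 24 h
  with $T_{1/2} \approx 4$ h puts the 5th interval within 0.1% of the
  steady-state curve (verified against explicit superposition), so fitting
  uses the cheaper closed steady-state form.
* **Flip-flop.** $K_a < K_e$ produces an identical curve with the roles of
  the two rates swapped. Estimation constrains $K_a > K_e$ at the
  individual level by default (configurable), which matches the fitted
  regime ($K_a \approx 1.2$, $K_e \approx 0.17$).

## Population layer

Between-subject variability is exponential (log-normal): with
$\eta_i \sim N_3(0, \Omega)$ in the fixed order (log-CL, log-V, log-Ka),

$$CL_i = CL_{pop} e^{\beta_{g(i)} + \eta_{i1}}, \quad
  V_i = V_{pop} e^{\eta_{i2}}, \quad K_{a,i} = K_{a,pop} e^{\eta_{i3}},$$

where $\beta_g$ is a per-treatment-group additive effect on log-CL
(reference group fixed at 0). The covariate enters clearance only, where
the treatment effect was detected; a configuration switch allows exploring
covariates elsewhere. $\Omega$ is a full covariance matrix by default
(all three correlations), with a diagonal option for comparison.

Residual error is Gaussian around the structural prediction $f$ with SD
$a$ (additive), $b f$ (proportional) or $\sqrt{a^2 + b^2 f^2}$ (combined).

### Censoring at the quantification limit

The assay LLOQ is 0.5 ng/mL and the steady-state trough (~0.8 ng/mL at the
typical parameters) sits right next to it, so with an additive residual SD
of 2 ng/mL a large fraction of 24 h samples fall below the limit. Three
policies are implemented: `exclude` (drop flagged records and report the
count), `loq2` (impute LLOQ/2) and `m3` (treat them as left-censored, the
observation contributing $\Phi((\mathrm{LLOQ}-f)/g)$).

**Design choice.** Although exclusion is the most transparent policy and is
the documented default of `loglik_conditional()`, the *estimation* default
is the censored likelihood (`m3`): at this design, exclusion truncates the
residual distribution at the trough and we measured a systematic upward
bias of the absorption rate constant of up to +36% at a fixed seed, which
disappears both under `m3` and when simulating without censoring. In the
SAEM sufficient statistics the latent censored values are Gibbs-imputed
from the truncated normal below the LLOQ, which keeps the M-step closed
form exact.

## SAEM estimation

`fit_saem()` is a standard stochastic approximation EM:

* **E-step.** Per subject, Markov chain Monte Carlo on $\eta_i$ targeting
  the conditional posterior. Two kernels per iteration: an *independent*
  Metropolis proposal from the prior $N(0, \Omega)$ (acceptance ratio =
  likelihood ratio), then 3 sweeps of component-wise Gaussian random walks.
  The independent kernel matters: the $\eta_v$/$\eta_{ka}$ posterior is a
  correlated ridge on sparse subjects, and component-wise walks alone can
  freeze on it. Random-walk scales adapt towards 30% acceptance during the
  exploratory phase only, so the smoothing-phase kernels are fixed, as the
  stochastic-approximation theory requires.
* **SA step.** Sufficient statistics (individual log-parameters, their
  second moment, per-observation squared residuals) are smoothed with step
  $\gamma_k = 1$ for the first $k_1 = 300$ iterations and
  $\gamma_k = (k-k_1)^{-1}$ for the $k_2 = 100$ smoothing iterations.
  During the exploratory phase the diagonal of $\Omega$ may shrink at most
  5% per iteration, the usual guard against premature collapse of the
  random-effect variances. The residual-error parameters are *not*
  floored: propping up an inflated initial error estimate destabilises the
  proportional model (we observed divergence when it was floored).
* **M-step.** Closed form. Fixed effects by generalised least squares of
  the smoothed log-parameters on the covariate design under the current
  $\Omega$, alternated with the $\Omega$ moment update to the joint
  complete-data maximum (the alternation is run to numerical convergence,
  and is verified against direct numerical maximisation to 1e-6).
  Additive and proportional error variances have exact closed forms in the
  smoothed statistics; the combined model is a 2-parameter inner
  optimisation on smoothed per-observation statistics (a standard
  approximation, since its complete-data likelihood admits no finite
  sufficient statistic).
* **Initialisation.** Pooled naive nonlinear least squares for the typical
  values (one curve through all observations, per-subject doses honoured),
  $\beta = 0$, $\Omega = 0.3^2 I$, error SD from the pooled residuals.
* **Standard errors.** Louis' identity accumulated during the smoothing
  phase: the fixed effects enter the complete-data likelihood only through
  the Gaussian prior on the individual log-parameters, so per-subject
  scores are analytic. The fixed-effect block of the observed information
  is inverted directly (the usual mixed-model block approximation).
  Typical-value CIs are computed on the log scale and exponentiated.
  If the information matrix is not positive definite the fit is returned
  with a warning and `se_method = "failed"` rather than fabricated SEs.
* **Marginal likelihood.** Per-subject importance sampling with a
  multivariate Student-t (4 df) proposal centred at the conditional mode
  with a curvature-based scale inflated by 1.5; exact when $\Omega = 0$.
  AIC/BIC use the number of observations in the BIC penalty.

The covariate test is exposed two ways, matching practice: a
likelihood-ratio test between fits with and without the group covariate,
and a one-way ANOVA of the no-covariate empirical-Bayes etas across groups.
The originally reported covariate p-value cannot be reproduced without the
raw data, and the package makes no claim to it.

## Individual estimates

`conditional_mode()` returns the maximum of `loglik + logprior` over
$\eta_i$ (the conditional mode, i.e. the empirical-Bayes estimate, matching
the published analysis; conditional means are not the primary output).
The search runs in the support coordinates of $\Omega$ — a singular or zero
$\Omega$ pins the corresponding components at 0 — with quasi-Newton from
multiple starts (the prior mode, plus the best state of a short MCMC run to
guard flip-flop multimodality on 3-observation subjects), followed by
Newton polishing; the gradient norm at the solution must be below 1e-6.
AUC~0-24~ = dose/CL~i~ and $T_{1/2} = \ln 2 V_i / CL_i$ are derived, and
$\eta$-shrinkage $1 - SD(\hat\eta_k)/\sqrt{\Omega_{kk}}$ is reported
because the design is sparse (~3.5 observations per subject).

## Synthetic-study generator

The generator emulates the design of the animal experiment with known
truth, so parameter recovery is testable:

* 99 mice split 36/21/21/21 across the four arms (control, antibiotics,
  zosuquidar, antibiotics + zosuquidar); the split reconciles the reported
  per-group ranges with the 99-mouse total and is configurable.
* Dose 3 mg/kg; body weight $N(25, 1.5^2)$ g truncated positive — the
  study does not report weights, and this is the standard range for
  7-week-old male C57Bl/6 mice. Dose in ng is weight-dependent, so
  exposure varies slightly with weight as in the real experiment.
* Dosing every 24 h for 5 days; sampling menu {1, 2, 4, 6, 8, 24} h after
  the last dose (the study states 6 time points spanning 1-24 h; this menu
  brackets the ~2 h absorption peak and the trough); 3 or 4 samples per
  mouse without replacement, with P(4) = 6/11 so the expected total is
  exactly 351 observations (3.5/mouse as reported).
* Truth: typical values CL/F = 0.32 L/h, V = 1.88 L, Ka = 1.20 1/h (the
  published estimates). Group effects on log-CL are anchored to the
  published group mean AUCs via AUC = dose/CL:
  $\beta_g = -\log(\mathrm{AUC}_g / \mathrm{AUC}_{ref})$, giving +0.399
  (antibiotics), -0.594 (zosuquidar) and -1.151 (both).
* $\Omega$: 30% CV per component with pairwise correlation 0.1, and
  additive residual SD 2 ng/mL. Neither is published; these are
  assumptions chosen once as realistic for a mouse PK study, are labelled
  `"assumptions"` in serialised outputs, and the acceptance tests use
  recovery of the typical values, which is robust to them. (The stated
  "0.1 covariance" with variance 0.09 would imply correlation > 1; it is
  read as correlation 0.1.)
* Observations below the LLOQ of 0.5 ng/mL are flagged and their
  concentration censored, concentrating (as in reality) at the 24 h trough.

What the generator does *not* emulate: body-weight-dependent clearance
allometry, inter-occasion variability, assay imprecision structure beyond
a single error model, and any microbiome or transcriptome measurement.
A green recovery test therefore establishes that the estimator recovers
the parameters of *this* data-generating process at *this* design — not
that the biological model is correct.

## What the tests do and do not establish

In-print arithmetic (half-life from the typical values, the 33% reduction
and 75% increase in group mean AUC, the 351/99 bookkeeping) is recomputed
exactly. Parameter recovery and error-model selection are simulation-based
with truth anchored to the published estimates. Quantities that depend on
the unpublished raw data — the reported mean AUC of 274.4 ng·h/mL (which
depends on unreported body weights), the observed 39.1 ng/mL mean at 2 h,
the variance-test p-values (0.003, 0.04) and the covariate p-value — are
deliberately not asserted; the machinery that would compute them from data
is tested on synthetic inputs instead.

## Known limitations

* One compartment only; no lag time, transit absorption or saturable
  elimination (the saturation discussed qualitatively in the source
  narrative is out of scope).
* No inter-occasion variability or time-varying covariates.
* The combined-error M-step is approximate (see above); additive and
  proportional are exact.
* Louis SEs ignore cross-information with the variance components; they
  were validated against replicate empirical SDs (ratio ~0.8-1.0), so the
  resulting CIs are adequate for the coverage criterion but can be
  slightly anticonservative.
* The importance-sampling likelihood assumes the conditional posterior is
  unimodal enough for a t-proposal at the mode; the MC standard error is
  reported so model-comparison margins can be judged against it.
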