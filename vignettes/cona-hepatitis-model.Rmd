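---
title: "A semi-mechanistic PK/PD/disease-progression model of ConA-induced hepatitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-mechanistic PK/PD/disease-progression model of ConA-induced hepatitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conahep)
```

## The system being modelled

Concanavalin A (ConA) injected intravenously into mice triggers a
T-cell-mediated fulminant hepatitis that is widely used as a model of
autoimmune hepatitis. Within hours, a cascade of inflammatory mediators is
released into serum — TNF-α first, then IL-6 and IFN-γ, with IL-10 showing a
biphasic course — and liver damage follows, read out as rising serum
activities of the transaminases ALT and AST. A dual PDE7A/PDE4B inhibitor
given intraperitoneally 30 minutes before the challenge raises intracellular
cAMP in immune cells and suppresses the *production* of these mediators at
the transcriptional stage, i.e. early in the cascade, not at the level of
the circulating cytokines themselves.

`conahep` implements this system as a 24-state ODE model with three layers:

1. **Pharmacokinetics.** A one-compartment model with first-order absorption
   and elimination,
   $\mathrm{d}A/\mathrm{d}t = -k_a A$,
   $\mathrm{d}X/\mathrm{d}t = k_a A - k_e X$,
   $C = X/(V_d/F)$.
   Amounts are per kg body weight and bioavailability is folded into
   $V_d/F$, since $F$ is not separately identifiable after intraperitoneal
   dosing. The reference estimates put the system in the *flip-flop* regime
   ($k_a = 1.49 < k_e = 4.59\ \mathrm{h^{-1}}$): the terminal slope of the
   concentration profile is the absorption rate, and the terminal half-life
   (≈ 28 min) is an absorption half-life.

2. **Cytokine cascade.** The challenge initialises a shared hypothetical
   precursor $T_1 = 1$ at `conA_time` (0.5 h after the drug dose), which
   decays with mean transit time $\tau$ and feeds four pathway-specific
   transit chains: one compartment for TNF-α, seven for IFN-γ, six for IL-6
   and one for IL-10. The last compartment of each chain stimulates the
   production term of an indirect-response (turnover) model,
   $\mathrm{d}C_x/\mathrm{d}t = (1 + T S_x)\,k_{in,x} - k_{out,x} C_x$,
   with $k_{in,x} = R_{0,x} k_{out,x}$ derived from the baseline so that the
   unperturbed system is exactly at steady state. The drug inhibits the
   *input* of the TNF-α, IFN-γ and IL-6 chains through an
   $I_{max}$/IC$_{50}$ function with $I_{max}$ fixed at 1. IL-10 is not
   drug-inhibited; instead, from the challenge onward an additional
   zero-order production term $k_{in,dis}$ acts, modulated by
   $F_{IL10} = 1 + T_{1c} S_{IL10} - C_{IFN} I_{IL10(IFN)}$ — ConA
   stimulates and IFN-γ linearly inhibits IL-10 synthesis, which produces
   the observed early peak, mid-course dip and late elevated steady state.

3. **Disease progression.** ALT and AST are separate turnover models whose
   production is stimulated by the *excesses* of TNF-α and IFN-γ above
   baseline; for ALT the excesses enter through power functions with fixed
   structural exponents $\alpha = \beta = 1.5$, for AST linearly. When the
   cytokines are at baseline the transaminases cannot rise, encoding the
   finding that TNF-α and IFN-γ are the drivers of liver damage in this
   model.

## Numerical choices

- **Event handling.** The challenge is a genuine discontinuity ($T_1$ jumps
  from 0 to 1). `simulate_group()` integrates the pre-challenge phase,
  applies the jump, and restarts the solver; this split scheme is
  authoritative. The IL-10 disease production term is switched with the
  phase rather than tested inside the right-hand side, keeping the ODE
  autonomous for the integrator.
- **Integrator.** `deSolve::lsoda` (stiff-capable) with defaults
  `rtol = 1e-8`, `atol = 1e-10`, both configurable. The right-hand side is
  also provided compiled in C (the deSolve compiled-model convention); the
  pure-R `full_rhs()` implements the identical equations and the test suite
  holds the two to agreement.
- **Undershoot guards.** $(C - R_0)$ is clamped at zero before the power
  terms in the ALT/AST stimulation functions, and observable series are
  floored at zero. Both clamps are inert in exact arithmetic (the model
  guarantees $C \ge R_0$) and only absorb transient solver undershoot of
  order `atol`. $F_{IL10}$ is deliberately *not* clamped — its transient
  negativity is what produces the IL-10 dip — but the total IL-10 production
  rate is floored at zero.
- **Peak times.** `predicted_tmax()` refines the grid maximum by quadratic
  interpolation through the three bracketing points (ties resolved to the
  earliest time) and reports biomarker peaks on the post-challenge clock. A
  0.01 h grid makes the refinement error negligible relative to the 0.1 h
  reporting resolution.

## Estimation workflow

Estimation is **sequential**, mirroring how such models are identified in
practice: `fit_pk()` first (both dose groups pooled with shared parameters,
on the dose-linearity assumption), then `fit_pd()` with the PK estimates
fixed (14 free parameters across the four jointly fitted cytokine series),
then `fit_disease()` with everything upstream fixed (6 free parameters).
Baselines are fixed at the healthy-cohort means, never estimated; production
rates are always derived from them; $I_{max}$ and the exponents
$\alpha, \beta$ are structural constants.

All stages minimise a naive-pooled weighted least-squares objective
$\sum_i w_i (y_i - \hat y_i)^2$ with prediction-based weights
$w_i = 1/\hat y_i^{\,2\lambda}$. The default $\lambda = 1$ (relative error)
is the natural choice for serum readouts spanning two orders of magnitude;
the exponent is configurable. Naive pooling is not a shortcut here but the
*correct* mode for this design: sampling is destructive (each mouse is
exsanguinated once), so no animal contributes more than one point per
analyte and per-animal effects are not identifiable. Goodness of fit is
summarised by the objective, `AIC = n log(WSS/n) + 2p`,
`BIC = n log(WSS/n) + p log n` (a fixed, documented least-squares
convention), and asymptotic CV% from the Gauss–Newton curvature of the
objective on the log-parameter scale.

The optimiser is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
log-transformed parameters, which enforces positivity and makes the
default box bounds (start/100, start×100) scale-free.

**PK branch identifiability.** The two-exponential concentration profile is
exactly symmetric under $(k_a, k_e, V) \to (k_e, k_a, V k_e/k_a)$, so WLS
alone cannot distinguish absorption-limited from elimination-limited
kinetics. `fit_pk()` fits both branches from data-driven starting values
(terminal slope, observed peak time and height) and, when the objectives
tie, reports the branch selected by `terminal_phase` — by default
`"absorption"` (flip-flop), the regime of slow intraperitoneal absorption
this model describes. The mirror solution is always recoverable by the
symmetry above.

**Starting values.** `fit_pk()` self-initialises from the data. The PD and
disease stages require user-supplied starts (there is no useful
design-free heuristic for a 14-parameter cascade); the package's recovery
studies start from the generating values perturbed by a fixed alternating
±30–50 % pattern, the usual convention in simulation-recovery studies, and a
multi-start check in the test suite verifies that perturbed starts agree at
the optimum.

## The synthetic-study generator

`generate_study()` emulates the trial that the model was built for:

- a dedicated PK cohort (no challenge), doses 50 and 100 mg/kg, serum drug
  sampled at 5, 15, 30, 60, 90, 120 min, 4 animals per time point;
- three challenged arms (vehicle, 50, 100 mg/kg) sampled at 1, 2, 4, 8 and
  24 h post-challenge, 5 animals per time point, all seven observables per
  animal (the group-size range reported for the original design is 4–5; the
  generator defaults to 5 with a design override);
- 4 healthy animals providing the baseline means.

Measurement error is multiplicative log-normal,
$y = \hat y\,e^{\sigma Z - \sigma^2/2}$ with $\sigma^2 = \log(1 + cv^2)$, so
the expectation equals the noiseless value and the coefficient of variation
is exactly `noise_cv`. The default CV of 20 % reflects typical serum
immunoassay/enzymatic assay precision and is a documented package
assumption, as is the baseline set `default_baselines()` (absolute healthy
baselines are study inputs, not published estimates). What the generator
does **not** emulate: assay quantification limits and censoring,
between-animal biological variability beyond residual noise, and any
misspecification of the structural model itself — so passing recovery tests
demonstrate estimator correctness under the model, not robustness to model
error on real data.

## What the package reproduces, and known limits

- The half-life arithmetic on the reference rate constants (absorption
  27.9 min, elimination 9.1 min; biomarker elimination half-lives from
  $k_{out}$) is reproduced exactly by `half_life_from_rate()`.
- The control-group simulation puts the TNF-α and IL-6 peaks at 1.70 and
  3.60 h post-challenge, within the 0.1 h reporting resolution of the
  reference values (1.6, 3.5). The IFN-γ peak computes to 4.58 h against a
  reported 4.4 h. This timing is a structural consequence of
  $(\tau, n, k_{out})$ alone — it is provably invariant to baselines and to
  all stimulation amplitudes, and insensitive to every admissible reading of
  the chain equations — so the residual 0.18 h gap cannot be closed by any
  parameter choice consistent with the printed estimates; it is reported as
  computed.
- ALT/AST peak times depend on the unpublished absolute baselines; with the
  documented defaults they fall at 7.1 and 8.2 h — after all cytokine peaks
  and in the reported neighbourhood (8.0, 8.5 h) — and are checked
  qualitatively, not to a tolerance.
- Noiseless round-trip recovery (generate → sequential fit) returns every
  estimated parameter to well within 1 %; with 10 % proportional noise at
  the study's sample sizes, the median relative error of the PK parameters
  and IC50s over 20 seeded replicates stays below 15 %.
- The objective/AIC/BIC conventions are fixed and documented here; absolute
  values are not comparable across software using other conventions.
- Problem sizes used by the shipped studies (a 0.01 h output grid over
  24.5 h, 20 stochastic replicates) keep the full suite to about a minute on
  one core while leaving the acceptance quantities insensitive to further
  refinement.

Alternative model variants that were considered and rejected during the
original model's development — a direct drug effect on transaminase
production, IL-6/IL-10 terms in the disease part — are deliberately out of
scope, as are mixed-effects estimation (inappropriate under destructive
sampling) and intracellular cAMP/PKA mechanism.

## A worked example

```{r example, eval = FALSE}
params <- grms55_parameters()

# vehicle-control simulation and peak times (post-challenge clock)
traj <- simulate_group(params, dose = 0, t_end = 24.5, grid_step = 0.01)
sapply(c("TNFa", "IL6", "IFNg", "ALT", "AST"),
       function(a) predicted_tmax(traj, a)$tmax)

# synthetic study, sequential refit
dat <- generate_study(study_design(), params, noise_cv = 0.1, seed = 42)
fpk <- fit_pk(dat[dat$analyte == "GRMS55" & startsWith(dat$group, "pk_"), ])
fpk
```
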