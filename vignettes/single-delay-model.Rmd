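---
title: "Assessing insulin sensitivity from the IVGTT with the Single Delay Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing insulin sensitivity from the IVGTT with the Single Delay Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivgttsdm)
```

## The problem

A frequently sampled intravenous glucose tolerance test (IVGTT) injects a
0.33 g/kg glucose bolus at time zero and samples plasma glucose (mM) and
insulin (pM) at 23 fixed times from -30 to 180 minutes; the three pre-bolus
samples are averaged into the basal values $G_b$ and $I_b$.  The clinical
question is a single number: how strongly does a unit of circulating insulin
accelerate glucose disposal in this subject?  The classical decoupled
Bergman Minimal Model (MM) answer, $S_I = p_3/p_2$, is notoriously fragile:
in heterogeneous populations a large fraction of fits give either
"zero-$S_I$" point estimates or implausibly large values, with confidence
intervals containing zero.  The Single Delay Model (SDM) addresses this by
fitting glucose *and* insulin simultaneously with six free parameters, one
of which *is* the insulin sensitivity index.

## The model

The SDM couples the two concentrations through

$$\frac{dG}{dt} = -K_{xgI}\, I(t)\, G(t) + \frac{T_{gh}}{V_g},\qquad
\frac{dI}{dt} = -K_{xi}\, I(t) +
  \frac{T_{igmax}}{V_i}\,\phi\!\big(G(t-\tau_g)\big),$$

with pancreatic response
$\phi(G) = (G/G^*)^{\gamma} / \left(1 + (G/G^*)^{\gamma}\right)$:
half-maximal at $G^*$, Michaelis–Menten for $\gamma = 1$, increasingly
sigmoidal for larger $\gamma$, and constant $1/2$ (an unresponsive
pancreas) at $\gamma = 0$.  The bolus appears as jump initial conditions
$G(0) = G_b + G_\Delta$ and $I(0) = I_b + I_{\Delta G} G_\Delta$ over the
constant pre-bolus history $G \equiv G_b$ on $[-\tau_g, 0)$, and the basal
steady state ties the two zero-order terms to the rest of the parameters:

$$T_{gh} = K_{xgI}\, I_b\, G_b\, V_g, \qquad
T_{igmax} = K_{xi}\, I_b\, V_i / \phi(G_b).$$

Only the ratios $T_{gh}/V_g$ and $T_{igmax}/V_i$ enter the dynamics.  The
six free parameters are $K_{xgI}$ (min$^{-1}$pM$^{-1}$, the insulin
sensitivity index itself), $K_{xi}$ (min$^{-1}$), $\tau_g$ (min), $\gamma$
(dimensionless), $G_\Delta$ (mM) and $I_{\Delta G}$ (pM/mM).

Two quantities are configuration constants rather than estimated
parameters.  $G^*$ defaults to 9 mM — roughly the glycemia at which
second-phase secretion saturates — because the source literature defines
the symbol but never reports estimating it; it is exposed as an argument
everywhere.  $V_i$ defaults to 0.25 L/kgBW; since only
$T_{igmax}/V_i$ is dynamically relevant this choice provably cannot change
any simulated or fitted concentration, and the test suite asserts that
invariance.  $V_g$ is recovered from the dose as $D_g/G_\Delta$, with
$D_g$ = dose / 0.18016 g/mmol.

## Simulation

`simulate_sdm()` integrates the delayed system by the method of steps:
mandatory breakpoints at every multiple of $\tau_g$ (the initial jump
propagates a derivative discontinuity to $k\tau_g$), classical fourth-order
Runge–Kutta inside segments (maximum step `h`, default 0.1 min), and a
cubic-Hermite dense history that supplies the lagged glucose between nodes.
At the single ambiguous point $s = t - \tau_g = 0$, where the solution
jumps, a step *ending* at $\tau_g$ sees the pre-bolus limit $G_b$ while the
step *starting* there sees $G_b + G_\Delta$; getting this two-sided
convention right is what preserves the integrator's fourth-order accuracy
across the breakpoint.  $\tau_g = 0$ degenerates to an ordinary ODE handled
without breakpoints.  Against a brute-force fixed-step Euler oracle the
trajectories agree to better than $10^{-4}$ relative at every schedule
time; the integrator's self-convergence error at the default step is below
$10^{-9}$.  During estimation the step is relaxed to 0.5 min: the
integration error there (~$10^{-8}$ relative) is six orders of magnitude
below the 1.5% measurement noise, and the looser step keeps a full cohort
fit inside seconds rather than minutes.

The MM comparator (`simulate_mm()`, `wls_fit_mm()`) follows the decoupled
convention: glucose before 8 min is disregarded, $G(8) = G_0$ is estimated
with the remote action $X(8) = 0$ (the literature does not state the
remote-compartment start), and the insulin input is the piecewise-linear
interpolation of the observed samples from the first post-bolus peak
onward.  Before the peak the input is held at the peak value — the sources
say only that pre-peak samples are disregarded, not what replaces them;
because the glucose objective starts at 8 min and insulin peaks by 2–4 min,
this choice has negligible leverage, and it is configurable.

## Estimation

`gls_fit_sdm()` implements two-phase generalized least squares.  Phase 1
minimizes
$\sum_{a}\sum_j (y_{aj} - \hat y_{aj})^2 / (CV_a\,\hat y_{aj})^2$ over the
log-transformed free parameters (positivity by construction; box bounds
$\gamma \le 10$, $\tau_g \le 60$ min keep the simulator well-conditioned —
physiological plausibility, not a literature value) with an L-BFGS-B
quasi-Newton search and a compiled central-difference gradient.  Phase 2
re-estimates the per-analyte error CVs from standardized residuals
$(y-\hat y)/\hat y$, with residual degrees of freedom apportioned to each
analyte in proportion to its share of the observations.  The phases
alternate until the parameter vector moves less than $10^{-4}$ relative
and the CVs less than 0.05 percentage points, or 10 iterations; fits that
do not converge are returned flagged, never dropped — the extreme-value
accounting downstream needs them.

The asymptotic covariance is $(J^\top W J)^{-1}$ at the optimum, with $J$
the central-difference Jacobian in log-parameters, mapped to the natural
scale by the delta method; because log-scale standard errors are natural
relative errors, the per-parameter CV% is $100\sqrt{\mathrm{diag}}$ of the
log-scale covariance directly.  A parameter is graded *identifiable* when
its CV is below 52% — the point at which the standard error reaches
$1/1.96$ of the estimate and the asymptotic confidence region touches
zero.  A singular information matrix reports infinite CVs rather than an
error.  For the MM, $S_I$'s CV comes from the delta method on $p_3/p_2$
using the log-scale covariance of the pair; $p_3$ may reach its lower
bound, reproducing the zero-$S_I$ phenomenon with an honestly enormous CV.

The phase-1 objective uses the *current* model prediction in the weights
(an extended-least-squares reading of the GLS family).  At the 1.5–7%
error CVs relevant here the difference from fixed-weight reweighting is far
below sampling noise; the reading matches the objective as specified.

## Indices

For each subject the panel assembles: $K_{xgI}$ (the SDM estimate,
verbatim); $S_I = p_3/p_2$; HOMA-IR $= G_b \cdot (I_b/c) / 22.5$ with $c$
the pM-to-uIU/mL conversion — an assay convention the sources never state,
defaulting to 6.0 and logged with every run; the acute insulin response
AIR $= I_\Delta / K_{xi}$ with $I_\Delta = I_{\Delta G} G_\Delta$ (a figure
caption in the source literature prints AIR $= I_{\Delta G}/K_{xgI}$,
contradicting the body text; the body-text definition is implemented, and
both are noted here rather than reconciled silently); and the disposition
index DI $=$ AIR $\times K_{xgI}$.  $S_I$ values $\le 1.5\times10^{-12}$ or
$\ge 3.99$ are flagged extreme — the Methods-style passage of the source
says "> 3" while the exclusion actually used starts at 3.99; the package
defaults to 3.99 and both thresholds are configuration.  BMI classes are
lean ($\le 24$), overweight ($24$–$30$], obese ($30$–$40$] and morbidly
obese ($> 40$).

## The synthetic cohort

No subject-level data accompany the source study, so `generate_cohort()`
emulates its population: per-class anchors (means and SDs of $G_b$, $I_b$,
BMI, height, and the class-mean $K_{xgI}$ from the published
anthropometric table) with class sizes 19/22/22/11.  Distributional shapes
are the generator's own choices, stated once: physiology from truncated
normals (BMI truncated to its class's defining interval so labels and
values agree; other variables to $\pm 2.5$ SD and positivity), $K_{xgI}$
log-normal with a 50% between-subject CV, the unreported kinetic
parameters uniform on plausible ranges ($K_{xi} \in [0.02, 0.12]$
min$^{-1}$, $\tau_g \in [5, 40]$ min, $\gamma \in [1, 5]$,
$I_{\Delta G} \in [20, 120]$ pM/mM), and $V_g$ normal around 0.16 L/kgBW
(30% CV — the default for parameters whose spread the sources do not
state) fixing $G_\Delta = D_g/V_g$.  Observation noise is independent and
multiplicative at 1.5% CV for glucose and 7% for insulin — the glucose
figure is the weighting CV used by the published MM procedure; the insulin
figure is a typical radioimmunoassay precision, since the sources estimate
but never print their insulin CVs.  Body weight derives from BMI and a
height draw so the dose in mmol/kgBW is meaningful.  An optional knob
correlates $I_b$ with $\log K_{xgI}$ (resistant subjects running
hyperinsulinemic); it defaults to off because the sources quantify no such
correlation.

What the generator deliberately does *not* emulate: assay drift between
laboratories, within-subject repeat-test variation, non-Gaussian error
tails, and any misspecification of the SDM itself — the generated kinetics
*are* SDM kinetics.  Passing recovery tests therefore demonstrates that
the estimation machinery is correct and well-calibrated under the model,
not that the SDM is the true data-generating process for human IVGTTs.
The MM-vs-SDM identifiability contrast inherits the same caveat in the
opposite direction: the MM is fitted to data it did not generate, which is
precisely the situation the comparison is meant to illuminate.

## Population analysis

`population_report()` reproduces the study's comparison structure:
per-class and total mean/SD/SE/N for each index on the full sample and on
the reduced sub-sample without extreme-$S_I$ subjects; Pearson (or
Spearman) correlations with pairwise deletion; Bland–Altman agreement on
the natural-log ratios $\ln(K_{xgI}/S_I)$ against pair means (log ratios
because the spread of differences grows with the index; natural base — the
sources do not state one); one-way ANOVA across BMI classes with Fisher's
LSD post-hoc contrasts, deliberately unadjusted for multiplicity (that is
what LSD means, and it matches the published reporting); and the
ordinary-least-squares regression of AIR on BMI.

## Numerical and design choices, collected

- Glucose molar mass 180.16 g/mol for the g-to-mmol dose bridge.
- Time origin at the bolus; pre-bolus samples only feed baselines.
- Fit bounds: $K_{xgI} \in [10^{-7}, 5\times10^{-3}]$,
  $K_{xi} \in [10^{-3}, 1]$, $\tau_g \in [0.1, 60]$,
  $\gamma \in [0.01, 10]$, $G_\Delta \in [0.5, 40]$,
  $I_{\Delta G} \in [0.5, 2000]$; MM $p_3 \ge 10^{-14}$ so the zero-$S_I$
  boundary is reachable.
- Data-driven starts: $G_\Delta$ from the glucose excursion,
  $I_{\Delta G}$ from the insulin excursion per mM, $K_{xi}$ from the
  log-linear slope of the last five insulin samples; flat records fall
  back to fixed constants with a warning.
- Insulin-peak ties break to the earliest time.
- Degenerate inputs (empty baselines, non-positive concentrations,
  non-monotone times, zero-variance correlations) raise classed errors
  naming the offending row; estimation failures degrade to flagged
  results, not exceptions.

Problem sizes used by the validation suite are chosen to exercise each
property at the smallest scale where its statistics are meaningful: 10
random parameter sets for solver equivalence, a 40-subject cohort for
recovery and the MM contrast, 50 replicates for error-CV calibration, 1000
null replicates for the ANOVA size, and 100 replicate cohorts of 5
subjects per class for the class-ordering check.  On the last of these, a
note: with the published class means only 1.23-fold apart for lean versus
overweight and a 50% between-subject CV, the probability that *sample*
class means order correctly is limited by information, not by estimation
quality — about two-thirds at 5 subjects per class, and only around the
0.9 mark at the study's own class sizes.  The test suite verifies both
bounds by direct Monte Carlo of the generator's sensitivity distribution.
The ordering check is reported at the small scale regardless; read its
failure rate as a statement about cohort size, not about the estimator.

## Limitations

The package treats the clamp-derived M index as an external covariate and
computes no HOMA2 (that index is defined by an external calculator
program; a pass-through column is provided, blanked below 20 pmol/L basal
insulin where the calculator is not applicable).  No Bayesian or
mixed-effects population estimation is attempted.  The delay is a single
discrete lag; distributed-delay and compartment-chain variants were
considered and rejected in the model-selection history the SDM emerged
from, and are out of scope here.
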