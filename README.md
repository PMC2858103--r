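# ivgttsdm

Insulin sensitivity from the frequently sampled intravenous glucose
tolerance test (IVGTT), assessed with the **Single Delay Model (SDM)** — a
two-compartment glucose–insulin system with a discrete delay in the
pancreatic response — together with the decoupled Bergman **Minimal Model
(MM)** comparator, basal surrogate indices, a synthetic cohort generator,
and the population-level statistics used to compare the methods.

It is written for quantitative physiologists and biostatisticians who need
a robust per-subject insulin sensitivity index from standard 23-sample
IVGTT records, and for methodologists studying why the classical MM
S<sub>I</sub> so often fails to be identifiable.

## The model

Plasma glucose *G* (mM) and insulin *I* (pM) evolve as

```
dG/dt = -K_xgI · I(t) · G(t) + T_gh / V_g
dI/dt = -K_xi · I(t) + (T_igmax / V_i) · φ(G(t - τ_g))
```

with sigmoidal pancreatic response `φ(G) = (G/G*)^γ / (1 + (G/G*)^γ)`,
jump initial conditions `G(0) = G_b + G_Δ`, `I(0) = I_b + I_ΔG·G_Δ` over
the constant pre-bolus history `G ≡ G_b`, and steady-state constraints
`T_gh = K_xgI·I_b·G_b·V_g`, `T_igmax = K_xi·I_b·V_i / φ(G_b)`.

The six free parameters `{K_xgI, K_xi, τ_g, γ, G_Δ, I_ΔG}` are estimated
from glucose **and** insulin simultaneously by two-phase generalized least
squares; `K_xgI` (min⁻¹pM⁻¹) *is* the insulin sensitivity index, in the
same units as the MM's `S_I = p3/p2`. A parameter is graded identifiable
when its asymptotic CV is below 52% (standard error under 1/1.96 of the
estimate). The delayed system is integrated by the method of steps with a
compiled fourth-order core.

## Worked example

```r
library(ivgttsdm)
set.seed(7)

# one synthetic subject per BMI class, at the study's noise levels
cohort <- generate_cohort(cohort_spec(
  n_per_class = c(lean = 1, overweight = 1, obese = 1, morbid = 1),
  seed = 7))

fit <- gls_fit_sdm(cohort$data[[1]])
tidy(fit)
#> # A tibble: 6 × 5
#>   term      estimate  std_error cv_percent identifiable
#>   <chr>        <dbl>      <dbl>      <dbl> <lgl>
#> 1 K_xgI     0.000113 0.00000137      1.21  TRUE
#> 2 K_xi      0.0385   0.000446        1.16  TRUE
#> 3 tau_g    10.6      0.0475          0.450 TRUE
#> 4 gamma     4.46     0.0687          1.54  TRUE
#> 5 G_delta  11.7      0.128           1.09  TRUE
#> 6 I_deltaG 30.6      0.442           1.45  TRUE
```

The lean subject's insulin sensitivity is estimated as
`K_xgI = 1.13e-4 min⁻¹pM⁻¹` with a 1.2% CV — comfortably identifiable;
`tau_g ≈ 11 min` is the apparent pancreatic delay and `G_delta ≈ 12 mM`
the theoretical glucose rise from the bolus. `glance(fit)` adds the
phase-2 error CVs (here 1.3% glucose, 3.0% insulin) and convergence
diagnostics.

Fitting the whole cohort with both models and assembling the index panel:

```r
sdm_fits <- fit_cohort(cohort, "sdm")
mm_fits  <- fit_cohort(cohort, "mm")
panel <- index_panel(sdm_fits, mm_fits, bmi = cohort$bmi)
dplyr::select(panel, subject_id, bmi_class, K_xgI, cv_K_xgI, S_I,
              inv_HOMA_IR, AIR, DI, sdm_identifiable)
#> # A tibble: 4 × 9
#>   subject_id bmi_class       K_xgI cv_K_xgI      S_I inv_HOMA_IR     AIR    DI
#>   <chr>      <fct>           <dbl>    <dbl>    <dbl>       <dbl>   <dbl> <dbl>
#> 1 S001       lean       0.000113       1.21 2.92e- 4       1.18    9301. 1.05
#> 2 S002       overweight 0.000428       1.46 1.00e-14       0.272   6863. 2.94
#> 3 S003       obese      0.00000710    31.1  1.15e-14       0.319 269183. 1.91
#> 4 S004       morbid     0.0000332      3.08 1.00e-14       0.690  11901. 0.395
```

Every `K_xgI` is identifiable, while the decoupled MM pins `p3` at its
lower bound for three of the four subjects — the "zero-S_I" phenomenon
the SDM was designed to avoid. `AIR = I_Δ/K_xi` is the acute insulin
response and `DI = AIR × K_xgI` the disposition index; `1/HOMA-IR` is the
basal surrogate. `autoplot(fit)`, `autoplot(panel)` and
`autoplot(bland_altman_log(...))` draw the standard figures, and
`population_report(panel, "reduced")` produces the class summaries,
correlations and log-ratio Bland–Altman agreement on the sub-sample
without extreme S_I values.

A command-line wrapper over the same pipeline lives at
`inst/cli/ivgttsdm.R` (subcommands `generate`, `fit-sdm`, `fit-mm`,
`indices`, `analyze`, `all`).

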