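# cetpkpd

Population pharmacokinetic-pharmacodynamic (PK-PD) modelling of an oral
cholesteryl ester transfer protein (CETP) inhibitor, for pharmacometricians
who want to exercise, re-estimate, or extend the published model chain of a
phase-I multiple-ascending-dose study (50/100/200/400 mg once daily for 14
days in healthy subjects) without access to the original clinical data.

CETP shuttles cholesteryl ester from HDL to apoB lipoproteins; inhibiting it
raises HDL-C and lowers LDL-C. The package implements the full model chain:

- **PK**: dose- and time-dependent relative bioavailability
  `F = Bmax (1 − D/(BA50 + D)) · exp(−α(D) t)` feeding a five-compartment
  Erlang transit chain (rate `Ktr`), first-order absorption (`Ka`), and
  three-compartment linear disposition (`CL/F`, `V/F`, `V2/F`, `V3/F`,
  `Q2/F`, `Q3/F`); the time decay `α` applies below 400 mg only.
- **CETP activity** (pmole): turnover model
  `dR/dt = Kin,base (1 + Kmax t/(K50 + t)) − kout R (1 + Emax Cp/(EC50 + Cp))`
  — an Emax placebo time effect on production and an Emax drug effect on
  loss, with `kout` tied by baseline stationarity (`kout = Kin,base/R(0)`).
- **HDL-C / LDL-C** (mg/dL): turnover models driven by CETP activity through
  a sigmoid Emax response `RES(R) = Rmax R^γ/(R^γ + R50^γ)` which
  *stimulates* HDL-C loss and *inhibits* LDL-C loss; LDL-C production
  carries a linear placebo ramp `β t`; `kdeg` is tied by baseline
  stationarity.

Around this core the package provides a synthetic-trial generator that
emulates the study design (32 subjects, rich day-1/day-14 sampling plus
daily troughs; log-normal inter-individual variability and per-endpoint
additive/proportional residual error at the published magnitudes), staged
pooled estimation (PK → CETP with individual PK fixed → lipids with
individual CETP fixed), bootstrap intervals, visual predictive checks, and
the fixed-effects dose-selection simulation against ±40% lipid targets.
The published estimates (the package's default truth set) are available as
`published_params()` and in `inst/extdata/published_params.yaml`.

## Worked example

Simulate the phase-I trial at the published estimates, re-fit the PK stage
from perturbed starting values, and run the dose-selection simulation:

```r
library(cetpkpd)

p  <- published_params()
ds <- synthesize_trial(default_design(), p, iiv = FALSE, noise = FALSE,
                       seed = 1)

fit <- fit_pk(ds, init = p, n_starts = 5, perturb = 0.3, seed = 11)
fit
#> Pooled PK stage fit: 1056 observations
#>   estimates:
#>     cl            6.40000
#>     v            11.28680
#>     v2           45.42490
#>     v3         1006.03000
#>     q2            2.60143
#>     q3            3.30010
#>     ka            1.08873
#>     ktr           1.09806
#>     ba50         90.10000
#>     alpha_low     0.00200
#>   fixed:
#>     bmax       1.6
#>   weighted SSR 7.40095e-18 | ELS objective 8172.72 | converged (22 iter)
```

A noise-free trial generated at the published values gives the published
values back: clearance 6.4 L/h, `BA50` 90.1 mg and `α₁` 0.002 1/h are
recovered essentially exactly, and `Ka`/`Ktr` to a fraction of a percent
(the five near-equal chain rates make their split the least identifiable
direction; `Bmax` is fixed as the identifiability anchor because oral data
only identify dose-scaled parameters).

```r
tab <- simulate_dose_grid(c(50, 100, 200, 400), n_days = 21, params = p)
target_attainment(tab)
#> Target attainment (HDL-C +40%, LDL-C -40%):
#>   dose_mg peak_hdl_pct peak_ldl_drop_pct hdl_attained ldl_attained both_attained
#> 1      50        60.11             47.41         TRUE         TRUE          TRUE
#> 2     100        72.39             53.89         TRUE         TRUE          TRUE
#> 3     200        80.50             57.75         TRUE         TRUE          TRUE
#> 4     400        94.18             62.43         TRUE         TRUE          TRUE
#>   minimal dose attaining both: 50 mg
```

At population fixed effects, 21 days of 400 mg once daily raises HDL-C by
about 94% and lowers LDL-C by about 62% at their peaks — comfortably past
the 40% targets used for dose selection. Peak effects grow monotonically
with dose, and the 50–200 mg arms lose effect after ~10 days of dosing as
their bioavailability decays with time, while 400 mg (no decay term) holds
its response.

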