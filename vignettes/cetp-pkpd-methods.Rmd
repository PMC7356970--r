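---
title: "Methods: sequential PK-PD modelling of a CETP inhibitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential PK-PD modelling of a CETP inhibitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cetpkpd` implements the population pharmacokinetic-pharmacodynamic model
chain of an oral cholesteryl ester transfer protein (CETP) inhibitor studied
in a phase-I multiple-ascending-dose trial in healthy subjects, together with
everything needed to exercise that chain end to end without access to the
original clinical data: a synthetic-trial generator emulating the study
design, staged pooled estimation, bootstrap and visual-predictive-check
diagnostics, and the fixed-effects dose-selection simulation against the
40% lipid-change targets.

Because the clinical dataset is not public, the package's quantitative
claims are *self-consistency* claims: trials simulated at the published
parameter estimates, re-fitted with the package's own estimation machinery,
must give those estimates back; and the fixed-effects simulation must
reproduce the published dose-selection conclusion.

# Model chain

## Pharmacokinetics

Drug amounts follow a linear compartment system: an administered dose enters
a chain of five transit compartments, each draining at the transit rate
$k_{tr}$ (an Erlang absorption delay), then an absorption compartment
draining at $k_a$ into the central compartment of a three-compartment
disposition model (apparent parameters $CL/F$, $V/F$, $V_2/F$, $V_3/F$,
$Q_2/F$, $Q_3/F$). Plasma concentration is the central amount divided by
$V/F$, scaled mg/L to ng/mL.

The amount actually absorbed from each administration is the dose times a
relative bioavailability
$$F(D, t) = B_{max}\Bigl(1 - \frac{D}{BA_{50} + D}\Bigr)\, e^{-\alpha(D)\,t},$$
evaluated once per administration at its time $t$ (hours since the first
dose). The time-decay coefficient is dose-group specific: $\alpha_1$ below
the 400 mg threshold, and 0 at or above it, reflecting the observed loss of
exposure under repeated dosing in the lower cohorts only. With the default
parameters $F$ ranges from about 1.03 (50 mg, day 1) down to about 0.29
(400 mg), so "relative" bioavailability can exceed 1; only dose-scaled
(apparent) parameters are identified from oral data.

## CETP activity

CETP activity $R$ (pmole) follows a turnover model,
$$\frac{dR}{dt} = K_{in,base}\,(1 + P(t)) - k_{out}\, R\, (1 + E(C_p)),$$
with an Emax placebo effect of time on production,
$P(t) = K_{max} t / (K_{50} + t)$ (a study-wide trend attributed to the
standardized in-house diet, applied to *all* arms), and an Emax drug effect
on loss, $E(C_p) = E_{max} C_p / (EC_{50} + C_p)$. The loss term is
first-order in $R$; $k_{out}$ is not an independent parameter but is tied to
baseline stationarity, $k_{out} = K_{in,base} / R(0)$, the standard
turnover-model initialization (the reported tables give the baseline and
production rate only, and a zero-order reading of the loss term would drive
activity negative within minutes at the reported maximal drug effect).

With $K_{50}$ some twenty times the study span, the placebo model operates
in its near-linear regime: $K_{max}$ and $K_{50}$ are individually poorly
identified (only their ratio is well constrained) and no test asserts their
separate recovery.

## HDL-C and LDL-C

Each lipid follows its own turnover model driven by CETP activity through a
sigmoid Emax response
$RES(R) = R_{max} R^\gamma / (R^\gamma + R_{50}^\gamma)$:
$$\frac{d\,HDL}{dt} = K_{syn} - k_{deg}\, HDL \,(1 + RES(R)), \qquad
\frac{d\,LDL}{dt} = K_{syn}(1 + \beta t) - k_{deg}\, LDL\,(1 - RES(R)).$$
CETP activity *stimulates* HDL-C loss and *inhibits* LDL-C loss, so
suppressing CETP raises HDL-C and lowers LDL-C. LDL-C production carries a
linear placebo ramp $\beta t$ (placebo LDL-C drifted upward during
hospitalization; placebo HDL-C was stable, so HDL-C has no placebo term).
As with CETP, $k_{deg}$ is tied by baseline stationarity at the reference
CETP activity $R_{ref}$ (the baseline activity of the linked CETP model):
$k_{deg} = K_{syn} / (rb\,(1 + RES(R_{ref})))$ for HDL-C and
$K_{syn} / (rb\,(1 - RES(R_{ref})))$ for LDL-C. The latter requires
$RES(R_{ref}) < 1$; parameter validation rejects sets that violate it.

A note on units: the reported tables label the lipid production constants
$h^{-1}$, but a zero-order production into a concentration must carry
mg/dL/h; the package uses mg/dL/h throughout.

## Variability model

Inter-individual variability is exponential:
$\theta_i = \theta \cdot e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$, on
$CL/F$, $V_3/F$, $B_{max}$, $k_{tr}$ (PK), $K_{in,base}$, $E_{max}$ (CETP),
baseline HDL-C, and baseline LDL-C, $\beta$, $\gamma$ (LDL). A reported CV%
is interpreted as $100\,\omega$ (the small-CV convention of exponential IIV
reporting); whether the original analysis used the exact log-normal
conversion is not knowable from the publication, and no claim of fidelity is
made beyond this convention. Derived rates are re-derived per individual so
every simulated subject starts at its own steady state.

Residual error is combined additive + proportional per endpoint
($\sigma_{add}$, $\sigma_{prop}$): proportional 0.30 for concentration
(additive fixed at a negligible 0.0001), 40.4 + 0.112 for CETP activity,
additive 4.6 mg/dL for HDL-C (the reported proportional entry is a garbled
fixed zero and is implemented as 0), and proportional 0.07 for LDL-C (the
reported table fixes the additive term at 0, which wins over the prose's
"combined structure").

# Synthetic-trial generator

`default_design()` encodes the study: four cohorts (50/100/200/400 mg once
daily for 14 days), 6 active + 2 placebo subjects each; all four endpoints
sampled at 0,1,2,3,4,5,6,7,8,10,12,18,24 h on day 1 and at the same offsets
plus 32,48,72,96,120,144,168 h after the day-14 dose, with daily pre-dose
troughs on days 2-13 (480 h span). The day-1 24 h sample and the day-2
trough are the same nominal instant; both records are kept so per-subject
record counts equal the configured schedule sizes. The published per-endpoint
observation totals do not factorize into any obvious per-subject schedule,
so the schedule is fully configurable and no total is hard-coded.

Placebo subjects receive no dose records and their drug concentrations are
represented as missing rather than zero. Drug concentrations below the
1.0 ng/mL quantification limit are flagged (`BLQ`) and excluded from fitting
by default (M1-style), configurably. The generator is deterministic under a
seed, byte-identically so.

What the generator does *not* emulate: covariate distributions (no covariate
entered any final model), dropout, dosing-history errors, assay drift, or
any between-endpoint correlation of residual errors. Passing recovery tests
therefore show that the estimation machinery is consistent with the model
chain under the study design - not that the model is correct for real data.

# Numerical methods

*PK.* The PK system is linear and time-invariant between impulses, so three
routes coexist: (i) a stiff-capable ODE solver (`deSolve::lsoda`,
rtol 1e-8 / atol 1e-10, restarted at dose events) - the reference path of
`simulate_pk` and the coupled subject simulator; (ii) exact discrete
propagation on a uniform grid - one Pade matrix exponential of $M\,dt$
applied stepwise with boluses added on grid points - used by the fitting
forward model (exact, and an order of magnitude faster than repeated ODE
solves); (iii) a per-time matrix-exponential evaluation used as the
independent single-dose oracle. The transit chain repeats the eigenvalue
$-k_{tr}$ five times, so the rate matrix is defective and an
eigendecomposition route is deliberately not attempted. Routes agree to
better than 1e-5 relative; the clearance identity $AUC = F D / CL$ is
verified by quadrature.

*Turnover stages.* Given a concentration (or CETP) input, both PD stages are
linear time-varying ODEs $dX/dt = a(t) - b(t)X$. The fitting forward model
and the staged simulation engine solve them with an unconditionally stable
exponential (integrating-factor) integrator on a uniform grid - Simpson
quadrature of the log integrating factor and of the forced integral, exact
for constant coefficients with O($dt^4$) quadrature error otherwise. Inputs
are interpolated by cubic Hermite polynomials with *exact* nodal derivatives
(from the rate matrix, or the turnover right-hand side), which matters: the
concentration rise after a dose is so convex that linear interpolation at
dt = 0.25 h leaves 0.2-1% errors in downstream CETP activity, while the
Hermite form stays below 0.01%. The coupled reference engine integrates all
twelve states in one `lsoda` system; staged and coupled engines agree to
well under 0.1% and a test enforces it.

Grid steps: 0.125 h for the staged simulation engine, 0.25 h for the
fitting forward models, 0.5 h inside the VPC simulator (bands are
percentile summaries; sub-0.1% trajectory accuracy is not needed there).

*Estimation.* The stage criteria are weighted least squares with fixed
residual weights $\sigma^2_{add} + (\sigma_{prop}\, y_{obs})^2$ evaluated at
the *observations*. The extended-least-squares form with prediction-based
variance (exposed as `els_objective` and reported with every fit) is not
used as the minimization criterion: its log-variance term is not minimized
at the generating parameters on noise-free data (it rewards under-prediction
by roughly $\sigma_{prop}^2$, ~9% for the PK stage), which would defeat the
package's recovery-based validation; with fixed observation weights the
noise-free optimum is exactly the truth, and on noisy data the two criteria
are asymptotically equivalent at these error magnitudes. Optimization is
Levenberg-Marquardt (`minpack.lm`) on log-transformed parameters (an
unconstrained parameterization that enforces positivity), chosen over a
bounded quasi-Newton because the criteria are least squares with an exact
zero-residual optimum in the validation setting, where LM converges faster
and much more precisely. Multi-start (default 5 starts, each the
initialization perturbed by independent U(0.7, 1.3) factors, seeded) guards
against the near-flat ridges ($k_a$ vs $k_{tr}$; $K_{max}$ vs $K_{50}$).

*Identifiability.* $B_{max}$ multiplies every dose identically, so it trades
off as a pure scale against the apparent clearances and volumes; it is fixed
during pooled PK estimation (the identifiability anchor, default: its
initialization value). The 400 mg decay coefficient is structurally 0; if a
dataset contains no lower cohort, $\alpha_1$ is automatically fixed and
flagged, as are the drug-effect parameters when a dataset contains no drug
exposure. The loss rates $k_{out}$/$k_{deg}$ are never free - they follow
the baseline-stationarity ties throughout estimation.

*Sequential fitting.* The CETP stage takes each subject's PK parameters as
fixed inputs, and the lipid stages take the PK + CETP parameters; in a
nonlinear mixed-effects analysis those would be empirical-Bayes individual
estimates. The package's stand-ins are the generating individual parameters
(for simulation studies) or pooled/two-stage estimates; `two_stage()`
summarises per-subject fits as CV% comparable to the reported omega values.
How faithful this is to the original sequential hand-off cannot be
quantified without the original data.

# Diagnostics

`bootstrap()` resamples subjects with replacement stratified by cohort,
refits from the point estimates, and reports 2.5/50/97.5 percentiles.
`vpc()` simulates replicate trials under the dataset's own design and bins
by nominal sampling time (the design times), pooling subjects; with
variability off, all bands collapse onto the model prediction. Self-simulated
data must fall inside the 5th-95th band about 90% of the time, and the test
suite checks 85-95% coverage on a full-design CETP VPC.

# Dose selection

`simulate_dose_grid()` runs the full chain at population fixed effects (no
IIV, no residual error - as in the original analysis) for 21 once-daily
doses, output to 504 h, and converts lipids to percent change from the model
baseline (the t = 0 value, not a pre-treatment average). Placebo time
effects are included in active simulations, consistent with the final model
equations. `target_attainment()` reports, per dose, whether the maximal
HDL-C increase and LDL-C decrease reach 40%, and the minimal dose attaining
both. Under the published parameters the 400 mg arm exceeds both targets;
the 50-200 mg arms lose effect after about ten days of dosing as their
bioavailability decays, while 400 mg (no decay) does not - both features are
asserted by tests.

# Problem sizes and study conditions

The acceptance-level checks use the full 32-subject design: a noise-free,
IIV-free trial for deterministic recovery (pooled fits from +/-30% perturbed
starts, 5 multi-starts); ten seeded full-variability replicates for the
stochastic baseline checks (single-start fits from the published values;
staged generation engine for speed); 100 simulated trials for VPC coverage;
20 random parameter draws within +/-50% of the published PK values for the
ODE-vs-oracle equivalence. Unit-level fitting tests run on a reduced
two-cohort, eight-subject, seven-day design. Bootstrap behaviour is tested
via the degenerate identity resample, stratification counts and
median-vs-point checks at 10 resamples rather than a full coverage study,
which would cost hundreds of refits. The two-stage CV-recovery check uses 24
subjects with variability on clearance only.

# Known limitations

- Pooled least squares is not FOCE-I: no shrinkage, no omega/sigma joint
  estimation, and pooled estimates under full IIV carry finite-sample bias
  from population heterogeneity (visible as a few-percent downward pull on
  the pooled LDL-C baseline under 23.6%/97.4%/50.9% CVs on baseline, slope
  and steepness). The reported bootstrap intervals comfortably absorb it.
- Objective-function values are not comparable to the originally reported
  NONMEM objective-function values.
- The mean transit delay implied by five transit compartments at the
  reported $k_{tr}$ is several hours; the originally reported Tmax of
  roughly 1 h cannot be reconciled with it, and no check is built on Tmax.
- The originally reported maximal lipid-change ranges (160-190% HDL-C
  increase, 47-66% LDL-C decrease) are not derivable from the fixed effects
  plus the stationarity closure, and no check is built on them.
- Extrapolation beyond the healthy-volunteer, three-week, standardized-meal
  setting (in particular the time-dependent bioavailability and placebo
  trends) is deliberately out of scope.
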