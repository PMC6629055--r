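---
title: "Modelling low-grade oligodendroglioma response to temozolomide: methods and design choices"
author: "lgoTMZ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LGO response to TMZ: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

WHO grade II oligodendrogliomas (LGO) are slow-growing, incurable glial
tumors whose volumetric response to temozolomide (TMZ) unfolds over
years: slow pre-treatment growth, a decline during and well beyond the
treatment course, and eventual regrowth. An instantaneous-kill model
cannot produce the long post-treatment decline; `lgoTMZ` therefore
splits the tumor into two compartments,

$$
\begin{aligned}
\frac{dP}{dt} &= \rho P\left(1 - \frac{P+D}{K}\right)
               - \alpha_1 P C - \alpha_2 P C,\\
\frac{dD}{dt} &= -\frac{\rho}{\kappa} D\left(1 - \frac{P+D}{K}\right)
               + \alpha_1 P C,\\
\frac{dC}{dt} &= -\lambda C,
\end{aligned}
$$

where $P$ is the proliferative tumor volume (cm³), $D$ the volume of
lethally damaged cells, and $C$ the TMZ concentration in tissue
(µg/cm³). Proliferative cells grow logistically towards a carrying
capacity $K$ shared with the damaged compartment. The drug acts
linearly on exposure: a fraction $\alpha_2 P C$ dies immediately
(necrosis, autophagy, drug-induced apoptosis) and a fraction
$\alpha_1 P C$ is moved into $D$, where cells survive until they
attempt mitosis and die by mitotic catastrophe — hence $D$ decays at
the *division* rate $\rho/\kappa \,(1 - (P+D)/K)$, with $\kappa$ the
mean number of division attempts before death. The slow decay of $D$
is what produces the months-long response after the last dose.

Two notational readings of the damaged-compartment decay coefficient
circulate ($\rho\kappa$ versus $\rho/\kappa$); we implement $\rho/\kappa$,
which is the biologically meaningful reading (more division attempts
before death means *slower* removal), and note that at the default
$\kappa = 1$ the two coincide.

Oral TMZ dosing is described as concentration impulses: at each dose
time $C \mapsto C + C_0$, with $P$ and $D$ continuous. This is
justified by scale separation — absorption and distribution complete
within about two hours, while the model's other time scales are weeks
to years.

The observable on T2/FLAIR MRI is the total volume $V = P + D$: both
compartments occupy tissue until damaged cells are actually removed.
Fitting and the survival threshold both use $V$.

## Parameters, units, defaults

| Parameter  | Meaning                                | Unit | Default |
|------------|----------------------------------------|------|---------|
| $P_0$      | proliferative volume at $t_0$          | cm³  | fitted (cohort 6.4–145) |
| $\rho$     | proliferation rate                     | day⁻¹ | fitted (cohort 3.3e-4–2.3e-3) |
| $\alpha_1$ | damage (delayed death) rate            | cm³/(µg·day) | fitted (cohort 0.01–1.99) |
| $\alpha_2$ | direct kill rate                       | cm³/(µg·day) | fitted (cohort 0.05–0.75) |
| $K$        | carrying capacity                      | cm³  | 523.6 (5 cm-radius sphere, ~2/5 brain volume; not identifiable from series, held fixed) |
| $\kappa$   | divisions before mitotic-catastrophe death | — | 1 |
| $\lambda$  | TMZ tissue elimination rate            | day⁻¹ | 8.3184 (half-life ≈ 2 h) |
| $C_0$      | effective per-dose tissue concentration | µg/cm³ | 0.6 (peak concentration for 150 mg/m²) |

The per-dose concentration is set directly to the literature peak
tissue concentration rather than assembled from dose, body surface and
a brain-delivery fraction; those factors are never separately
identifiable from volumetric data and are absorbed into $C_0$.

Survival analyses use a lethal threshold of 280 cm³ (an 8 cm sphere —
somewhat above the ~7 cm fatal burden estimated for more aggressive
gliomas) and censor at 25 years; both are arguments, not constants.
Time is days throughout the dynamics; survival output is in years with
1 year = 365 days.

## Numerics

The right-hand side is compiled C called through `deSolve`. Integration
uses `lsoda`/`lsodar` at `rtol = 1e-8`, `atol = 1e-10`; we chose the
livermore family over an explicit Runge–Kutta because it combines
adaptive error control with built-in *event* handling (each dose stops
the integrator, increments $C$, and restarts — impulses are never
smuggled into the right-hand side as narrow spikes) and, in `lsodar`,
root detection used to locate the threshold crossing $P + D = 280$
directly. Accuracy is verified in the test suite against two
independent oracles: the drug-free logistic closed form (agreement to
1e-6 relative over 25 years) and a fixed-step Euler reference at
$h = 10^{-4}$ day over a 30-day window containing an impulse
(1e-3 relative). Simultaneous doses are summed into one impulse.
Degenerate inputs follow explicit contracts: a patient already at the
threshold gets event time 0; a threshold at or above $K$ is rejected
(unreachable under logistic dynamics); censoring returns the horizon
with `event = FALSE`, and a Kaplan–Meier median that is never reached
is reported as `NA`, not as the horizon.

## Schedules

All regimens are built from 5-day dosing blocks:

* `standardSchedule(n)`: 28-day cycles, doses at cycle offsets 0–4
  ("days 1 to 5" encoded with the first dose at the cycle start, so
  $t = 0$ is the first administration).
* `longCycleSchedule(n, restDays)`: the rest lengthened beyond 23 days;
  `longCycleRestSweep()` gives the 12 studied rests 23, 38, …, 188 days.
* `distributedSchedule(n, variant)`: the five doses redistributed
  within the 28-day cycle (alternate days 0,2,4,6,8, or evenly spaced
  0,4,8,12,16; the "one dose every 4 days" wording also admits a 0–24
  reading, exposed via `firstDose`).
* `combinedSchedule()`: the 5+12 scheme — 5 induction cycles given
  monthly plus 12 maintenance cycles every three months. "Month" is
  taken as 28 days and "three months" as 84, for consistency with the
  standard cycle; maintenance spacing is measured start-to-start. Both
  conventions are arguments, and we verified that the plausible
  alternatives (30/90-day months, end-to-start spacing) change the
  cohort's median twin benefit by well under 0.1 year.

## Fitting

Free parameters are $(P_0, \rho, \alpha_1, \alpha_2)$; $K$ and
$\kappa$ stay fixed ($K$ is not identifiable from a single volume
series — a broad range of $K$ fits equally well with slightly shifted
parameters). The objective is unweighted least squares on absolute
volumes at the observation times (a relative-residual variant is
available but off by default). Because a single local search is
initialization-sensitive, `fitPatient()` runs a seeded Latin-hypercube
multi-start (default 20 starts) of bounded L-BFGS-B searches on
unit-box-scaled parameters, then polishes the best start. Bounds
default to the cohort ranges widened by about half: $P_0 \in [1,300]$,
$\rho \in [10^{-4}, 5\times10^{-3}]$, $\alpha_1 \in [0,3]$,
$\alpha_2 \in [0,1.5]$. One numerical point deserves note: the default
finite-difference step of L-BFGS-B is far too coarse for a patient
whose $\alpha_1$ is near zero (the step would exceed the parameter
itself), so the gradient step is set to 1e-6 of the scaled box. With
that, noiseless synthetic series from every cohort parameter set are
recovered to well within 1% relative on all four parameters.

## Virtual trials

Virtual patients are drawn uniformly and independently from the
cohort's representative box
($\rho \in [0.5,2.5]\times10^{-3}$ day⁻¹, $\alpha_1 \in [0.01,1]$,
$\alpha_2 \in [0.1,0.75]$ cm³/(µg·day), $P_0 \in [20,200]$ cm³,
$K \in [300,550]$ cm³, $\kappa = 1$). Trials are *paired*: the same
patients receive both arms' schedules, so any survival difference is
attributable to the schedule alone. The reference design gives arm A a
per-patient uniform random 5–18 standard cycles (the range spanned by
the real cohort; only the range is documented, so the integer-uniform
draw is our choice) and arm B the 5+12 scheme, with death at 280 cm³
and 25-year censoring. Arm comparisons use the Kaplan–Meier medians,
the two-sample log-rank test, and a Cox proportional-hazards fit on
the arm indicator (the standard companion to a log-rank comparison;
the source analysis does not name its HR estimator) with Efron tie
handling and a Wald 95% CI. Power sweeps rerun independent trials per
size with sub-seeds spawned from one master seed, a 10-year follow-up
and censoring of patients alive at follow-up.

Twin analyses compare each fitted cohort patient under its actual
cycle count (standard spacing) against the 5+12 scheme, both with
treatment starting at $t = 0$ — the lag between first scan and
treatment start is not documented per patient, and we verified the
benefit is insensitive to it — and a 200-year horizon instead of the
usual censor, because a well-controlled slow tumor can stay below
threshold for decades. The "survival of the real patient" is the
simulated time-to-threshold of the twin under the patient's cycle
count; the actual clinical dosing calendars (gaps, delays, missed
doses) are not available, which is the main caveat when comparing
cohort-level benefit numbers against the published analysis.

## Synthetic cohorts

The generator emulates the statistical structure the fitting stage
assumes: logistic pre-treatment growth, response during and after
treatment, and regrowth, sampled at a clinical cadence (default: scans
every 90 days, 3 before treatment, 4 during, 10 after) with
multiplicative lognormal measurement noise. The noise law is
parameterized so its coefficient of variation equals the 18%
discrepancy of manual ellipsoidal volumetry
($V = D_1 D_2 D_3 / 2$) against semi-automatic segmentation;
lognormality guarantees positive volumes and a mean multiplier of 1.
What the generator does *not* emulate: real scan-interval
irregularity, treatment interruptions, inter-rater measurement drift,
or any departure of real tumors from the model family itself. Passing
parameter-recovery tests on synthetic cohorts therefore demonstrates
identifiability and correctness of the pipeline, not clinical validity
on real series.

## Problem sizes used in the checks

The test suite fits all 11 cohort parameter sets from noiseless
synthetic series (5 optimizer starts each), runs the scaled virtual
trial at 250 patients/arm, the power comparison at 20 and 100
patients/arm with 20 trials each, type-I calibration of the log-rank
from a 600-patient simulated pool with 1000 resampled 20-vs-20 null
trials (resampling from a fixed pool keeps the null exact while
avoiding hundreds of thousands of ODE solves), and long-cycle
non-inferiority over 10 rest lengths on a 500-patient sample. The
acceptance script runs the full 1000-per-arm trial. These sizes were
chosen so each quantity's Monte-Carlo spread is small relative to the
effect examined.

## Known limitations

* Linear exposure–response; no saturating ($E_{max}$) dose–response,
  so conclusions hold for re-spacing a fixed dose, not dose escalation.
* No spatial structure (reaction–diffusion), systemic pharmacokinetics,
  toxicity, or resistance/persister dynamics.
* $K$ is fixed by convention; fitted parameters are conditional on it.
* The lethal-volume threshold is a modelling surrogate for death, not
  a clinical endpoint.
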