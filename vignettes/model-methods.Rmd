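---
title: "Model and methods: nivolumab plus chemotherapy in advanced gastric and esophageal adenocarcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastricCEA)
```

## The decision problem

First-line nivolumab added to fluoropyrimidine/platinum chemotherapy prolongs
overall survival (OS) and progression-free survival (PFS) in advanced gastric,
gastroesophageal-junction and esophageal adenocarcinoma, but at a drug price
that may not be commensurate with the gain. `gastricCEA` implements a cohort
cost-effectiveness model comparing nivolumab + chemotherapy against
chemotherapy alone from the Chinese and the US payer perspective, and the
one-way and probabilistic sensitivity analyses that probe its robustness.

## Model structure

The model has three mutually exclusive health states — progression-free (PFS),
progressive disease (PD) and death — with the whole cohort entering in PFS.
State occupancy is obtained by **partitioned survival**: at time $t$,

$$\pi_{PFS}(t) = S_{PFS}(t), \qquad
  \pi_{PD}(t) = S_{OS}(t) - S_{PFS}(t), \qquad
  \pi_{death}(t) = 1 - S_{OS}(t),$$

which is the unique occupancy consistent with the three-state diagram and the
two survival curves, and requires no transition-probability estimates. A pair
of curves is accepted only if $S_{OS} \ge S_{PFS}$ on the whole model grid
(`validate_arm()` reports the first crossing time otherwise).

Time is discretised into 21-day cycles over a 10-year horizon —
$\lceil 10 \times 365.25 / 21 \rceil = 174$ cycles — and occupancy is
evaluated at **cycle midpoints**, which acts as a built-in half-cycle
correction. Whether the original analysis used any half-cycle correction is
not stated anywhere we could verify; midpoint evaluation is this package's
documented choice, and its discretisation error is below 0.5% of discounted
totals (tested against the closed-form exponential integral, and by halving
the cycle length).

Costs and effects are discounted at 3% per year with per-cycle factors
$(1.03)^{-t_{mid}}$ ($t_{mid}$ in years). Willingness-to-pay thresholds are
\$37,653/QALY in China (three times 2021 per-capita GDP) and \$100,000/QALY in
the US.

## Survival inputs

The published evidence reports per-arm median PFS and OS and the hazard
ratios (HR) of the intervention versus the comparator:

| population | arm | median PFS (mo) | median OS (mo) | HR PFS | HR OS |
|---|---|---|---|---|---|
| all randomized | nivolumab + chemo | 7.7 | 13.8 | 0.77 | 0.80 |
| all randomized | chemo alone | 6.9 | 11.6 | — | — |
| PD-L1 CPS ≥ 5 | nivolumab + chemo | 7.7 | 14.4 | 0.68 | 0.71 |
| PD-L1 CPS ≥ 5 | chemo alone | 6.0 | 11.1 | — | — |

No parametric family is named by the source analysis (it digitized the
published Kaplan–Meier curves). The medians are the only printed curve
summaries, and the exponential is the unique one-parameter family a median
identifies, so the default family is **exponential with
$\lambda = \ln 2 / \text{median}$**. Weibull least-squares fitting is
available whenever digitized coordinate files are supplied
(`fit_km_curve()`, unweighted least squares on the survival-probability
scale, with a moment/regression start and log-parameter optimisation).

**How the intervention arm is built was a genuinely open design choice.** Two
constructions are defensible from the printed inputs: (a) each arm from its
own medians, or (b) the comparator from its medians and the intervention via
the proportional-hazards relation $S_{int}(t) = S_{comp}(t)^{HR}$. Under
exponential curves the two disagree noticeably — the printed medians imply a
rate ratio of $6.9/7.7 = 0.896$ for PFS, while the estimated HR is 0.77 —
because trial medians are noisy summaries of the whole curve while the HR is
estimated from all events. Route (a) yields an incremental effectiveness of
only 0.159 QALYs in the all-randomized population, far below the 0.23 QALYs
implied by the published per-arm totals; route (b) yields 0.233 QALYs and
reproduces the published per-arm QALYs, incremental costs and ICERs closely
in every reported population and country. The package therefore uses the
**HR-based construction as the base case**
(`intervention_source = "hazard_ratio"` in `default_config()`), and keeps the
per-arm-medians route available as a scenario
(`intervention_source = "medians"`). The HR is applied to both endpoints;
the comparator arm always comes from its own medians.

## Costing

All unit prices carry a ±20% range and a Gamma tag. Doses in mg/m² are scaled
by the mean body surface area (1.72 m² China, 2.10 m² US), then:

* **Vial rounding** — intravenous doses are rounded up to the *cheapest
  covering combination of whole vials* (no vial sharing), found by exhaustive
  enumeration over at most $\lceil \text{dose}/\text{size}_i \rceil$ vials of
  each size. E.g. nivolumab 360 mg in China: 2×100 mg + 4×40 mg = \$5,345.82
  per administration. Oral drugs are rounded up to whole tablets per
  administration.
* **Backbone** — the trial allowed XELOX (3-week cycle) or FOLFOX (2-week
  cycle) by investigator choice, and the assumed mix is unpublished. The
  default is XELOX, whose cycle aligns with the model cycle; FOLFOX is a
  config option, normalised to the model cycle by the factor 21/14. Treatment
  runs for the whole PFS occupancy (treat-to-progression).
* **Nivolumab cap** — 360 mg every 3 weeks, stopping after 2 years: dosing in
  every model cycle whose start is before day 730.5, i.e. the first 35
  cycles.
* **Monitoring** — laboratory tests and a follow-up unit every cycle, one CT
  scan every second cycle. The source prices these items without stating
  frequencies; this schedule (≈6-weekly imaging) is the package's documented
  assumption. The CT is amortised as half a scan per cycle so that the PFS
  cost stream is constant outside the nivolumab window; against an
  alternating schedule this changes discounted totals by well under 0.1%.
* **Progressed state** — best supportive care + follow-up + laboratory tests
  per cycle; by default no active post-progression anticancer therapy (the
  assumed second-line mix is unpublished), but any priced drug can be
  configured as a PD-state regimen.
* **Adverse events** — grade 3–4 incidences enter as a one-off expected cost
  at model entry, for the three events with priced management (anemia,
  neutropenia, decreased neutrophil count); other listed events carry no
  price and contribute zero.

Infusion/administration fees, travel and indirect costs are not priced in the
source material and are excluded.

## Outcomes

Per arm, discounted QALYs accumulate
$(u_{PFS}\,\pi_{PFS,k} + u_{PD}\,\pi_{PD,k})\,\Delta\,d_k$ over cycles
($u_{PFS} = 0.797$, $u_{PD} = 0.577$, $u_{death} = 0$; $\Delta = 21/365.25$
years), and discounted costs accumulate the per-cycle streams weighted by
occupancy, plus the one-off adverse-event cost. `compare_arms()` forms
incremental cost and effect; the ICER is reported only in the quadrants where
it is interpretable, with dominance flags otherwise, and the net monetary
benefit $\mathrm{NMB} = \mathrm{WTP}\cdot\Delta E - \Delta C$ drives the
cost-effectiveness verdict.

## Sensitivity analysis conventions

Parameter ranges are ±20% of base unless a published range exists (the two
utilities). The (low, high) interval is read as a central 95% interval, so
$\sigma = (\text{high}-\text{low})/3.92$; Gamma (costs) and Beta (utilities,
incidences) hyperparameters follow by the method of moments. Every ±20%
Gamma parameter therefore has shape $ (1.96/0.2)^2 = 96.04$ regardless of its
base. Survival parameters are **held fixed** in both OWSA and PSA, matching
the reported tornado categories (costs and utilities only); HR-based survival
uncertainty would be a scenario analysis, not part of the default parameter
set.

The tornado (`owsa()`) re-runs the full pipeline with one parameter at a
bound and everything else at base, ranking by ICER span. The PSA
(`run_psa()`) draws all parameters jointly and independently for 1,000
iterations under a recorded seed (default 20230913); a draw that produces an
invalid configuration — e.g. a sampled PD utility above the sampled PFS
utility, which happens in roughly 2% of draws given the overlapping Beta
ranges — is rejected and redrawn (at most 100 retries, counted in the
result). The cost-effectiveness acceptability curve is the fraction of draws
with non-negative NMB across a WTP grid.

## Synthetic digitized curves

`generate_km_points()` emulates what a plot digitizer produces from a
published KM figure: evenly spaced survival readings from $t=0$ down to
$S \approx 0.05$, additive Gaussian noise on the survival scale, clipping to
$[0,1]$, a running-minimum monotone repair, and an anchored first point
$(0, 1)$. `generate_scenario()` wraps two arms of such point sets into a
runnable configuration with the generating truth recorded, which is how the
fitting and the coordinate-file input route are tested end to end (noiseless
coordinates must reproduce the medians route to within 0.1%; noisy
coordinates must recover generating rates to within a few percent).

The generator mimics digitization error only. It does not simulate
individual patient event times, censoring, number-at-risk attrition, or the
step structure of a real KM estimate — so passing recovery tests demonstrates
correct fitting and plumbing, not robustness to every artefact of real
digitized figures.

## Numerical choices and degenerate inputs

* Exponential fit: Brent on $\log\lambda$, started at the moment estimate
  $\overline{-\log s / t}$; Weibull: Nelder–Mead on log-parameters started
  from the $\log(-\log s)$ regression; non-convergence raises a fit-failure
  error rather than returning a partial answer.
* Identical PFS and OS curves are valid (PD occupancy identically zero);
  identical arms give $\Delta E = 0$ and a dominance flag, never a division
  by zero.
* PD occupancy within $-10^{-9}$ of zero is clamped to zero; anything lower
  is a curve-crossing error.
* Problem sizes used throughout the documentation and tests: 174 cycles,
  1,000 PSA iterations, 20–30 point digitization grids, 200 random instances
  for the vial-rounding cross-check.

## Known limitations

* Exponential-from-median curves carry no shape information; long-horizon
  tail behaviour (and immunotherapy's characteristic late plateau) is not
  represented. The China-perspective ICERs computed here sit ~10–12% below
  the published point values — consistent with unpublished digitized-curve
  shapes and costing conventions (second-line mix, imaging frequency,
  backbone mix) that printed inputs cannot pin down — while the incremental
  QALYs and the US-perspective ICERs agree within ~2%.
* The one-off adverse-event costing ignores grade 1–2 events and AE timing;
  the tornado confirms results are insensitive to these parameters.
* No correlation structure between sampled parameters; no value-of-information
  analysis; only two strategies are compared.
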