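---
title: "Methods: noncompartmental pharmacokinetics and toxicity grading for carboplatin HIPEC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noncompartmental pharmacokinetics and toxicity grading for carboplatin HIPEC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipecpk)
library(dplyr)
```

## The problem

During hyperthermic intraperitoneal chemotherapy (HIPEC) a heated carrier
solution containing carboplatin is circulated through the peritoneal cavity
for 90 minutes immediately after cytoreductive surgery. The clinical
questions are pharmacokinetic: how large is the local exposure advantage
(perfusate versus plasma), how quickly is the drug absorbed from the cavity
(does a 90-minute perfusion make sense?), does the extent of peritoneal
stripping change systemic uptake, and how much hematological toxicity does
the systemic exposure cause?

`hipecpk` implements the full analysis chain for a dual-matrix
concentration-time study of this design: validated table ingestion with
below-LLQ censoring, per-patient noncompartmental analysis (NCA), log-scale
cohort summaries, a two-group exposure comparison, CTCAE v4.0 grading of
serial blood counts, and a kinetic simulator that generates complete
synthetic cohorts for testing and teaching.

## Data model and LLQ policy

Concentration tables are long-format: one row per
(patient, matrix, time) with matrix either `perfusate` or `plasma`, time in
minutes from the start of perfusion and concentration in µg/mL. The sampling
grids mirror intensive clinical practice: perfusate at 0, 5, 7.5, 10, then
every 10 minutes to 90; blood every 15 minutes to 90 and again at 8, 16, 24
and 48 h after the start (480, 960, 1440, 2880 min).

The assay's lower limit of quantification (LLQ) is 0.01 µg/mL. A sample is
below LLQ (BLQ) when the file carries the literal token `"BLQ"` or a numeric
value under the LLQ. The analysis *excludes* BLQ samples — no zero or LLQ/2
imputation — because an unquantifiable value carries no usable magnitude;
imputation variants were deliberately not made the default. The 48-hour
plasma sample is essentially always BLQ (the plasma half-life of roughly
160 min means concentrations fall six orders of magnitude below their peak
by 48 h), so plasma profiles effectively end at 1440 min.

One consequence needs care: the plasma sample at t = 0 is predose and
therefore always BLQ. After exclusion the plasma profile starts at 15 min
and the perfusion-window AUC over [0, 90] would be uncomputable. `run_nca()`
therefore anchors the *rising* plasma limb at a zero origin (0, 0) for
integration only; Cmax and the terminal fit never see this synthetic point.
This is the standard predose-zero convention of NCA software.

## Noncompartmental analysis

Per patient and matrix the package computes:

* **Cmax / Tmax** — maximum observed concentration and the earliest time
  attaining it (ties resolve to the earliest sample).
* **λz and terminal half-life** — ordinary least squares of
  ln C on t over a terminal window; T½ = ln 2 / λz.
* **AUC90** — trapezoidal area over [0, 90] min in both matrices.
* **AUCtotal (plasma)** — area from 0 to the last quantifiable plasma time.
* **AUC ratio** — AUC90 perfusate / AUC90 plasma, the local-exposure
  advantage.

### Terminal-window selection

The terminal window always ends at the last quantifiable point, contains at
least three samples, and starts strictly after Tmax — the Cmax sample is
kept out so the absorption peak cannot flatten the fitted slope. A profile
that declines from its very first sample has no absorption peak, and there
the first sample is eligible (a drained perfusate profile is of this type).

Two selection rules are implemented:

* `"maximal"` (default): the largest such window with a declining slope.
* `"best_adj_r2"`: among all candidate windows, the one maximising the
  adjusted R², ties (within 10⁻⁴) going to the window with more points —
  the "best fit" convention of standard NCA software.

The default was a genuinely open design choice and we deviated from the
usual software convention on purpose. The adaptive best-R² rule exists to
keep a multi-exponential distribution phase out of the window. Both matrices
here decay mono-exponentially in their terminal phase (perfusate throughout
the perfusion; plasma at 8–24 h, long after absorption input has ceased),
and for a mono-exponential measured with proportional assay error the
log-scale noise is homoscedastic, so the *full* post-peak window is the
unbiased, minimum-variance choice. The adaptive rule, by contrast,
preferentially selects windows in which noise happens to steepen the
apparent decline (steeper slopes yield higher R² at equal noise), which
systematically shortens estimated half-lives on exactly this kind of data —
the package's own simulator makes the effect visible within a few cohorts.
`best_adj_r2` remains available for sensitivity analyses and for data with a
genuine distribution phase, and it is the variant validated against
exhaustive window enumeration in the test suite.

A fit is refused — and the half-life reported as missing, never guessed —
when fewer than three eligible points exist or no candidate window declines.
Per-patient failures never abort a cohort run; they are collected as notes.

### AUC computation

The default integrator is the plain linear trapezoid, the minimal reading of
"the trapezoidal method"; `linear_up_log_down` (log-linear segments on
declining stretches) is available behind a flag for sensitivity checks.
Window bounds falling between samples are interpolated consistently with the
chosen method, which makes the integral exactly additive over adjacent
windows. No extrapolation beyond the sampled range is ever performed — the
study design defines exposure over observed windows only, so there is no
AUC-to-infinity anywhere in the package.

## Cohort statistics

PK parameters are treated as log-normal, so the central tendency is the
**geometric mean** with an exponentiated t-interval on the natural-log
scale, exp(m ± t₍ₙ₋₁₎ s/√n). Dispersion is reported as median, range and an
order-statistic IQR (ranks ⌈(n+1)/4⌉ and ⌈3(n+1)/4⌉ — ranks 4 and 12 at
n = 15); this "observed value" quartile convention is the common one in
clinical PK reporting and is what the reference table uses.

The minor-versus-major peritonectomy comparison is an equal-variance
(Student's) two-sample t-test on ln(AUC ratio); the back-transformed
difference is the ratio of geometric means with its exponentiated CI.
Welch's variant is available via `var_equal = FALSE`. Raw p-values are
always reported; the conventional two-sided 0.05 level is applied only when
describing results in prose. No multiplicity adjustment is made — the design
has a single pre-specified comparison.

Reporting precision follows the clinical convention (concentrations,
half-lives and AUCs to the integer, the exposure ratio to one decimal) via
`format_summary_table()`; full precision is retained internally and rounding
is applied only at presentation time.

## Hematological toxicity

Serial complete blood counts (day −1 baseline, days 1–7, 14, 21, 30) are
graded against CTCAE v4.0 bands in the units of the laboratory: counts in
10⁹/L, hemoglobin in mmol/L. The grade-3 bands are pinned to the clinical
definitions — neutrophils [0.5, 1.0), platelets [25, 50), hemoglobin
< 4.9 mmol/L — and the remaining boundaries follow the published scale
(hemoglobin converted from g/dL; anemia has no numeric grade-4 laboratory
bound, so hemoglobin grading tops out at 3). A value exactly on a boundary
belongs to the *less severe* grade, matching the strict inequalities of the
scale; a value at or above the configurable lower limit of normal is
grade 0.

The attribution rule is the subtle part: hemoglobin and platelet drops seen
during surgery (day 0) or on postoperative day 1 reflect operative blood
loss and hemodilution, not chemotherapy. `assess_course()` therefore counts
anemia and thrombocytopenia only when the in-window nadir occurs after day 1
*and* lies below the day-1 value ("further decrease"); the day-0/1 event
itself is still recorded, flagged `counted = FALSE`. "Further decrease" is
interpreted as any decrement below the day-1 value that still reaches at
least grade 1 — a grade-crossing requirement would be an alternative, and
the day-1 comparison value is the natural configurable point if one wants
it. Neutropenia and leukopenia are counted anywhere in days 1–30.

## The synthetic-data generator

The simulator is a two-compartment catenary model: dose D enters the
perfusate at t = 0, transfers to plasma with first-order constant kₐ, is
eliminated from plasma with constant kₑ, and the perfusate is physically
removed at the 90-minute drain:

* perfusate amount: A_pf(t) = D·e^(−kₐt) for t ≤ 90, 0 after;
* plasma amount: A_pl(t) = D·kₐ/(kₐ−kₑ)·(e^(−kₑt) − e^(−kₐt)) up to the
  drain, pure elimination afterwards (the kₐ = kₑ limit D·kₐ·t·e^(−kₐt) is
  handled explicitly);
* concentrations are amounts over effective volumes V_pf and V_c.

The closed forms satisfy mass balance identically
(A_pf + A_pl + eliminated = D up to the drain), which the tests verify to
10⁻⁹ and cross-check against independent numerical ODE integration.

### Parameter defaults and why

| parameter | default | unit | rationale |
|---|---|---|---|
| kₐ | ln2/104 | 1/min | perfusate terminal half-life observed clinically (~104 min) |
| kₑ | ln2/160 | 1/min | plasma terminal half-life observed clinically (~160 min) |
| V_pf | 4.2 | L | dose/CmaxPF ≈ 1456 mg / 348 µg/mL; smaller than the 5 L carrier because saline is absorbed faster than drug, concentrating the perfusate |
| V_c | 15 | L | calibrated so the noiseless AUC ratio (~12.4) and plasma AUC90 (~1900 min·µg/mL) sit at the clinical geometric means; plasma Cmax then ~36 µg/mL, inside the observed 21–39 range |
| drain | 90 | min | perfusion time of the procedure |
| dose rule | 800, cap 1600 | mg/m², mg | the BSA dosing rule, cap at 2.0 m² |
| BSA | N(1.83, 0.21) on [1.42, 2.16] | m² | truncated normal matching the observed cohort |
| iiv_cv | 0.20 | — | lognormal interindividual CV; reproduces the observed spread (e.g. CmaxPF 279–595 across 15 patients) |
| assay_cv | 0.08 | — | proportional error under the assay's stated <10% CV |
| llq | 0.01 | µg/mL | assay LLQ |

V_c deserves a note: with kₐ, kₑ and V_pf fixed as above, a central volume
of 18 L would push the simulated exposure ratio to ~14.8, well away from the
clinical 12.3; 15 L puts the noiseless ratio at 12.4. It is a calibration
constant of this generator, not an estimate of carboplatin's distribution
volume.

Each patient draws lognormal (median-preserving) multipliers for kₐ, kₑ,
V_pf and V_c, evaluates the closed forms on the clinical schedules, applies
proportional lognormal assay noise and censors below the LLQ. Patient i's
random stream is derived deterministically from the master seed, so growing
a cohort never reshuffles existing patients. Group labels default to the
observed 9:6 minor:major and 4:11 upfront:interval proportions.

`simulate_cbc()` generates blood-count courses: baseline-normal values with
mild noise, an optional smooth dip whose nadir hits the midpoint of a
requested CTCAE grade band on a requested (scheduled) day, and an optional
surgery-type day-1 drop that recovers — the pattern the exclusion rule must
refuse to count.

### What the generator does and does not emulate

It reproduces: the sampling schedules, BLQ censoring (including the
always-censored 48 h plasma sample and predose zeros), the dosing rule, the
observed magnitudes and the interindividual spread of every perfusion-window
NCA parameter, and blood-count courses with controllable toxicity events.

It does **not** emulate: a plasma distribution phase (plasma is one
compartment, so simulated 8–24 h concentrations decay more slowly relative
to their 90-min value than real multi-compartment kinetics, and simulated
total-period plasma AUCs run higher relative to AUC90 than observed);
hyperthermia- or time-dependent absorption; protein-binding kinetics (total
drug only); transfusion effects on hemoglobin; or missing/irregular
sampling. Passing tests on simulated cohorts therefore validates the
*estimators and the pipeline*, not the physiological fidelity of the model
beyond the features listed.

## Numerical choices and degenerate inputs

* Terminal-fit tie tolerance 10⁻⁴ on adjusted R², ties to more points.
* Cmax ties resolve to the earliest time.
* Dose rounding to the nearest mg; the cap applies after scaling.
* Quartile ranks are clamped into [1, n] so n = 1 degenerates to the value
  itself.
* Grade boundaries are half-open below (boundary value → less severe
  grade).
* BSA draws use rejection sampling against the truncation interval.
* Empty or all-BLQ profiles raise explicit errors at the LLQ stage; a
  profile with under three quantifiable points keeps Cmax and AUC where
  computable and reports the half-life as missing.
* Off-schedule CBC nadir requests snap to the nearest scheduled day with a
  message.

## Problem sizes used in validation

The test suite works at desk scale by construction: cohorts of 15 (the
study size) for calibration checks, 100+ randomised profiles for the
window-selection oracle, 0.1-minute grids for closed-form AUC and half-life
recovery, and 10–15-patient blood-count cohorts for the toxicity rules.
`scripts/acceptance.R` re-runs the reference-cohort statistics and one
seeded 15-patient simulation end to end.

## Known limitations

* The reference per-patient tables are summaries of a 15-patient cohort;
  raw concentration-time data are not public, so per-patient NCA cannot be
  validated against real profiles — only against the simulator's closed
  forms and the published summary statistics.
* One recorded dose in the reference cohort (patient 14: 1296 mg at BSA
  1.63 m²) differs by 8 mg from the dosing rule applied to the printed BSA,
  presumably because the printed BSA is itself rounded; `check_dose_rule()`
  surfaces exactly this row.
* Simulated total-period plasma AUC is biased high relative to real data
  (single plasma compartment, see above); perfusion-window quantities are
  unaffected.
* CTCAE grading covers the four hematological toxicities only, and grade-4
  anemia (a clinical, not laboratory, definition) is not assigned.
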