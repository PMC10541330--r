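---
title: "The HRF/PH severity score: model, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HRF/PH severity score: model, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrfph)
```

## The score

The HRF/PH score grades the severity of persistent pulmonary hypertension of
the newborn (PPHN) on two axes measured at the time of the first complete
echocardiogram and sums them into a 0–15 integer.

**Oxygenation (HRF) axis, 0–5.** The axis is keyed on the escalation ladder
of respiratory support. On no support, nasal cannula or HFNC the infant
scores 0, or 1 once flow reaches 2 L/min or FiO₂ reaches 0.30. On any
positive-pressure mode (CPAP, NIPPV, IMV, HFOV — HFOV is scored through the
invasive branch, as invasive ventilation) the score is 2–5 by band lookup of
a severity index:

* oxygenation index, OI = FiO₂ × 100 × MAP / PaO₂, when an arterial blood
  gas exists within the gas window (default 4 h) of the echocardiogram;
* otherwise the oxygen saturation index, OSI = FiO₂ × 100 × MAP / SpO₂, from
  a preductal pulse-oximetry reading. Site preference is right upper limb >
  left upper limb > lower limb; among readings from the best available site
  the one nearest the echo is used, and of two equidistant readings the
  later one (the preference is a clinical rule; the nearest/later tie-break
  is ours, chosen so scoring is deterministic).

Units matter: FiO₂ is a fraction in [0.21, 1.0], SpO₂ a percentage, MAP in
cmH₂O, PaO₂ in mmHg. The record reader rejects percent-scale FiO₂ (> 1)
loudly rather than silently producing hundredfold-inflated indices, by far
the most damaging unit error this pipeline can receive.

**Echocardiographic (PH) axis, 0–10.** Four components, each an established
marker of right-heart pressure load or function:

* interventricular septal position grade 0–3 (normal bow into the RV, through
  systolic flattening, to bowing into the LV), taken as the cardiologist's
  ordinal read, never computed from images;
* TAPSE grade 0–3, lower excursion grading higher;
* estimated right ventricular systolic pressure, RVsP = 4v² (simplified
  Bernoulli on the peak TR jet velocity v in m/s), graded 0–3 against the
  systemic systolic pressure;
* one point for right ventricular dysfunction (present/absent).

When no TR jet is measurable — common in PPHN, and itself sometimes a sign of
poor RV contractility — the RVsP cannot be estimated and twice the septal
grade substitutes for the *combined* septum + RVsP contribution. We read the
doubling rule as a substitution rather than an addition on top of an intact
septal term: the additive reading would allow totals above 15, contradicting
the score's defined 0–15 range, while the substitution preserves it (and
makes the fallback exactly consistent with the jet path whenever the jet
would have graded equal to the septum, a property the test suite checks).

**Total.** HRF + PH, categorized mild (0–5), moderate (6–10), severe (11–15);
the bounds are inclusive and totals are integers by construction, so no
rounding is ever involved.

## Tunable parameters

Only the first OI/OSI band ("OSI < 5 or OI < 10 scores 2") and the NC/HFNC
thresholds are pinned down exactly by the published description; the
remaining cut points are reconstructions and therefore live in
`score_config()`, versioned and fully overridable:

| parameter | default | unit | rationale |
|---|---|---|---|
| `gas_window_hours` | 4 | h | stated gas-recency rule |
| `nc_flow_lpm`, `nc_fio2` | 2, 0.30 | L/min, fraction | stated thresholds |
| `oi_breaks` | 10, 15, 25 | – | first band as stated; upper bands at conventional escalation cut points (OI 15 ≈ moderate HRF, 25 ≈ severe; 40 is the classical ECLS-consideration threshold and sits inside the top band) |
| `osi_breaks` | 5, 7.5, 12.5 | – | half the OI cut points (OSI ≈ OI/2 convention) |
| `tapse_breaks_mm` | 6, 8, 10 | mm | anchored to published term-neonate reference values (normal term TAPSE ≈ 10 mm) |
| `rvsp_ratio_breaks` | 0.5, 2/3, 1.0 | ratio | sub-half-systemic / mild / near-systemic / systemic-or-suprasystemic, the conventional bedside strata |
| `vis_coefficients` | 1, 1, 10, 100, 100, 10000 | per µg/kg/min (U/kg/min for vasopressin) | the standard published VIS weighting |
| `category_breaks` | 6, 11 | – | printed category bounds |
| `tapse_default_mm` | unset | mm | a missing TAPSE is an error unless a site supplies an imputation policy |

All band tables are lower-inclusive/upper-exclusive with the top band closed
above, and cover [0, ∞) without gaps or overlaps by construction (they are
stored as interior break points, and the validator enforces strict
monotonicity).

## The cohort analysis layer

`cohort_analysis()` mirrors the outcome-by-severity-category table: for each
dichotomous outcome a category × outcome contingency table, Fisher's exact
p-value, and per-category count/denominator/percent; for each continuous
outcome per-category median and IQR and a linear regression on the category
index with HC1 robust standard errors. Conventions, stated because they are
not canonical:

* **Fisher, two-sided rule.** The two-sided p is the total probability of
  tables (under the observed margins) whose point probability does not
  exceed the observed one — the point-probability method. Point
  probabilities are compared with a 10⁻⁷ relative slack so floating-point
  noise cannot drop a tied table. 2×2 tables use hypergeometric tail
  summation; larger tables use the Freeman–Halton extension by full
  recursive enumeration, guarded to n ≤ 500 (the enumeration is exact, so
  no asymptotic approximation is ever substituted). A margin of zero
  contributes no information: such rows/columns are dropped, and a table
  left with a single row or column has exactly one attainable configuration,
  p = 1. An entirely empty table is an error.
* **Exact logistic regression is not implemented.** The conditional-
  likelihood machinery is out of scope; dichotomous associations are tested
  by Fisher exact on the same table, and an ordinary maximum-likelihood
  logistic fit is reported alongside, flagged `ml_logistic_non_exact`. With
  a zero-event category the ML fit is separated and its p-value is not
  meaningful; the Fisher p is the one to read.
* **Predictor coding.** Regressions use the category index (1, 2, 3) as the
  predictor, matching an analysis "across the score categories"; the total
  score is an equally defensible coding, and `robust_ols()` accepts any
  design the user prefers.
* **Robust SEs.** HC1 (the n/(n−k) small-sample scaling), computed by
  `sandwich::vcovHC()` behind the `robust_ols()` surface, with t-based Wald
  p-values — the convention of Stata's `robust` option, which this analysis
  layer mirrors.
* **Quantiles.** IQRs use linear interpolation between order statistics
  (type 7, R's default); the published table cannot disambiguate the method.
* **Percent display.** Rounded half-away-from-zero to integers for report
  rendering; comparisons in tests allow ±1 percentage point to absorb the
  source table's own rounding.
* **Survivor denominators.** Several outcomes (ventilation-duration flags,
  lengths of stay, durations) are only defined among survivors; they are
  missing for patients who died, and `build_table()`/`summarize_outcome()`
  shrink denominators accordingly, reporting the exclusion count rather than
  silently dropping rows.

## The fixture cohort

Patient-level data behind the published tables are unavailable, so
`reconstruct_fixture()` rebuilds a deterministic 83-patient cohort from the
category-level constraints alone: category sizes (5/65/13); per-category
event counts for death-or-ECLS (0/12/10), ECLS (0/8/8), death (0/7/7), iNO
(1/50/13), vasoactive infusions (0/42/13), IMV (1/49/13), HFOV (0/41/13),
the ventilated-a-week-or-longer flags, sex (1/43/9 male), meconium
aspiration (1/25/4) and lung malformation (0/2/3). The died-and-ECLS overlap
per category follows by inclusion–exclusion (died + ECLS − composite:
moderate 3, severe 5, total 8 — matching the reported 8 of 14 deaths on
ECLS), and the builder refuses any specification whose implied overlap is
negative or exceeds min(died, ECLS), naming the violated identity.

Within a category, each record receives a total score from a fixed multiset
chosen to satisfy the published cohort summaries (range 2–12, mean 8.5):
mild {2,3,4,5,5}, moderate scores 6–10 with counts (8,12,15,15,15), severe
7 elevens and 6 twelves. Each total is then *inverted* into raw
measurements — support mode, FiO₂, MAP, PaO₂, SpO₂, septal grade, TAPSE, TR
velocity, systolic BP — that reproduce exactly that total when run through
the scoring pipeline, so the fixture exercises the calculator end to end
rather than carrying pre-baked scores. Continuous durations (iNO hours, IMV
days, lengths of stay, VIS, ECLS hours) are deterministic quantile-matched
reconstructions of the published per-category median/IQR anchors; they are
flagged *reconstructed, not target* — the printed medians are matched by
construction and assert nothing about real patients. (The severe-category
VIS upper quartile is garbled in our source rendering of the outcome table
and is reconstructed as 45; it is never asserted.)

The HFOV row only reconciles with its printed percentage (84% in the
moderate category) against the ventilated denominator (41/49), not the
column N; the fixture stores numerator and ventilated denominator explicitly
as the `hfov_ventilated` attribute and the analysis reports HFOV against
column N.

## The simulator

`simulate_cohort()` emulates the statistical structure the analysis assumes,
not real physiology: three latent severity strata mixed at the observed
cohort proportions (0.06/0.77/0.17), stratum-specific raw-input
distributions (uniform ranges for FiO₂, MAP, PaO₂ or SpO₂, TAPSE, TR
velocity, systolic BP; Bernoulli arterial-line availability, TR-jet absence
and RV dysfunction), and per-outcome event probabilities that are monotone
non-decreasing in the stratum, defaulted to the observed per-category event
rates. The default input ranges are deliberately well separated — each
stratum's attainable totals fall inside its own category band — because the
simulator's job is to verify that the end-to-end pipeline (CSV → typed
records → OI/OSI selection → band lookups → composite → category) preserves
a known ground truth, and a diagnostic `category_recovery` attribute reports
the fraction recovered.

What the simulator does **not** emulate: overlapping severity distributions
(real cohorts blur across category boundaries), correlated outcomes beyond
the death-or-ECLS composite, measurement error in echo reads, gestational-age
structure, or time-varying severity. A high recovery rate therefore
validates the plumbing and the monotone-link statistics, and says nothing
about the score's clinical discrimination on real patients.

All randomness flows through a single mandatory integer seed; a fixed seed
reproduces the cohort exactly.

## Problem sizes and numerical checks

The test suite cross-checks the Fisher implementation against an independent
brute-force enumeration oracle and against `stats::fisher.test`: every 2×2
table with n ≤ 30 is swept exhaustively against the hypergeometric closed
form, and 2×3 tables are swept exhaustively to n = 10 with a further seeded
random sample up to n = 30 — past that point the oracle's own enumeration
cost grows combinatorially while adding no new tie structure. Robust-SE
checks compare against a hand-coded sandwich formula at machine precision,
and against classical OLS standard errors in a balanced homoskedastic layout
(where HC1 is consistent for the same quantity) by simulation. Simulation
recovery is checked at n = 2000, large enough that a 95% recovery bound has
negligible Monte-Carlo risk under the default separation.

## Limitations

The default OI bands above score 2, the TAPSE cut points and the RVsP ratio
strata are reconstructions of an under-specified published figure; scores
computed with this package's defaults are faithful to the published
description where it is explicit and to conventional neonatal practice where
it is not, but they are not guaranteed to replicate the original scorers'
band edges. Every such edge is configurable precisely so a site can pin its
own. The VIS coefficient set is the standard published one; the source's
supplementary equation could not be checked against it. The analysis layer
deliberately implements no multivariable adjustment, survival analysis or
serial (repeated-echo) scoring.
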