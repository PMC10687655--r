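---
title: "Methods: a Markov cohort model of MRI-based prostate cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of MRI-based prostate cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriscreen)
```

## The decision problem

`mriscreen` implements a decision-analytic Markov cohort model comparing two
annual prostate-cancer screening strategies for men entering at age 65 with
an elevated serum PSA, over a 10-year horizon and from a federal-payer
costing perspective:

* **standard**: every screened man receives a PSA test and a TRUS-guided
  (standard) biopsy each year;
* **mri**: every screened man receives a PSA test and a prostate MRI each
  year; only men with a positive MRI go on to an MRI-guided biopsy.

Men are stratified by serum PSA (<2.5, 2.5–4.0, 4.1–10.0, >10.0 ng/mL). A
stratum fixes two parameters — the probability of harbouring prostate cancer
at entry and the annual post-treatment recurrence probability — and is
assumed not to change over the horizon. Outcomes are discounted expected
cost (2020 USD) and quality-adjusted life-years (QALYs); strategies are
compared by the incremental cost-effectiveness ratio (ICER) against a
$100,000/QALY willingness-to-pay threshold.

## State space

The cohort engine uses 13 states:

| state | meaning | annual cost | utility weight |
|---|---|---|---|
| `no_cancer` | cancer-free, screened annually | testing cost | 1 + testing decrements |
| `undx_{low,int,high}_{nc,c}` | undiagnosed cancer by grade and comorbidity, screened annually | testing cost | 1 + grade decrement + testing decrements |
| `treat_year1` | the treatment year | $19,319.33 (equal-thirds mix) | 1 − 0.119 |
| `post_treatment` | after the treatment year | $1,353 | 1 − 0.050 |
| `deferred_{low,int}` | diagnosed low/intermediate-grade disease with comorbidities, treatment deferred | $706 | 1 − 0.233 |
| `recurrence` | post-treatment recurrence (absorbing until death) | $1,353 | 1 − 0.320 |
| `death` | absorbing | 0 | 0 |

Within a cycle, events apply in a fixed order: background mortality →
screening/detection → grade progression. Detected high-grade disease is
always treated; detected low/intermediate-grade disease is treated unless
comorbidities are present, in which case treatment is deferred and resumed
only upon upgrading to high grade. Undetected and deferred disease upgrades
one grade per year with probability 0.250. Rewards are valued on
cycle-start occupancy with no half-cycle correction (switchable via
`pca_options(half_cycle = TRUE)`); cycle 0 is undiscounted and later
cycles are discounted at 3% per year.

Treatment modality is collapsed to an expected cost: equal thirds of
prostatectomy ($16,306), radiotherapy ($21,860) and brachytherapy
($19,792), i.e. $19,319.33. Modality affects only cost in the base case,
so the collapse is exact; per-modality costs remain in the registry for
sensitivity analyses.

## Diagnostic cascade

The standard arm biopsies every screened man; its detection probability for
a diseased man is the biopsy sensitivity (0.760). The MRI arm biopsies a
diseased man with probability `sens_mri` (0.760) and a cancer-free man with
probability `1 - spec_mri` (0.120); detection requires a positive MRI
followed by a positive MRI-guided biopsy, composed under conditional
independence (`0.760 × 0.900 = 0.684`). The composition rule is isolated in
one place and switchable (`pca_options(composition = "mri_only")`) because
published reports rarely state it.

False positives are transient: a cancer-free man with a false-positive
result incurs that round's testing cost and adverse-event disutility but is
not treated. The overtreatment variant (`fp_treated = TRUE`) exists for
exploration; with the published costs it inflates the standard arm's
expected cost in the lowest stratum several-fold beyond the published
value, which is why transient false positives are the default.

## Parameter registry and distributions

All inputs live in a YAML registry (`pca_default_config()`) with one record
per parameter: role, base value, 95% interval and distribution family.
Probabilities and test characteristics are beta; costs are gamma; utility
decrements are beta on the magnitude scale (fitted on |decrement| in
[0, 1] and negated on sampling — one convention for every decrement row,
whose support always contains the published interval). Fixed settings
(discount rate, horizon, treatment-mix weights, the willingness-to-pay
threshold) are point values.

Printed ranges are interpreted as central 95% intervals. Each distribution
is fitted by holding the mean exactly at the printed value and minimising
the squared distance between its (2.5%, 97.5%) quantiles and the printed
endpoints over the one free shape parameter (`stats::optimize` on the log
scale). With a single degree of freedom the two quantiles cannot always be
matched simultaneously: the worst case in the default registry is the
biopsy-cost row, whose fitted lower quantile sits about 5% of the interval
width inside the printed endpoint, and the >10 ng/mL prevalence row, whose
narrow asymmetric interval leaves the upper quantile about 2% of the width
outside. `fit_residuals()` reports every residual so the interval
convention stays auditable.

Two special cases: the MRI-guided biopsy specificity is printed as 1.000
(range 0.906–1.000); a mean-preserving beta does not exist at the boundary,
so it is held at its point value and does not vary in the probabilistic
analysis. The six joint grade-by-comorbidity probabilities are sampled
independently and renormalised to sum to one in every draw, preserving the
printed means while guaranteeing a valid categorical distribution.

Background mortality uses a bundled table of annual all-cause death
probabilities for US males aged 65–74 transcribed from a published period
life table; any table with columns `age`, `annual_death_probability` can be
substituted (`pca_options(mortality = ...)`). No prostate-cancer-specific
excess mortality is applied — no such probability is published for this
model — and this is the single most consequential structural assumption:
it caps how much expected QALY can differ between strategies through the
disease pathway.

## Charging the screening disutilities

The PSA-test decrement (−0.0002) is charged to every screened (alive,
undiagnosed) man each round in both arms. The biopsy adverse-event
decrement (−0.016 per event, with event probabilities 0.600 after a
standard biopsy and 0.400 after an MRI-guided biopsy) is charged as
probability-of-event × decrement on the biopsied fraction.

*When* it is charged was genuinely open, and the two candidate conventions
differ by an order of magnitude in their consequences. Charging it at every
annual round makes the standard arm lose ≈0.0098 utility per year; over a
discounted decade the MRI arm then gains ≈0.07 QALYs even in the <2.5
ng/mL stratum, which is 98% cancer-free — ten times the published
incremental QALY for that stratum (0.007) — and the ICER ordering across
strata inverts. Charging the expected decrement once, at the first
screening round, reproduces the published low-prevalence increments
closely (incremental cost ≈ $1,377 vs $1,264; incremental QALY 0.0087 vs
0.007; ICER $157,400 vs $187,558) and preserves the published strictly
decreasing ICER ordering. The near-disease-free stratum isolates this
convention from every other structural unknown, so the package defaults to
the first-round charge (`pca_options(ae_timing = "per_round")` switches
back).

## What the model reproduces, and what it cannot

With the defaults the base case reproduces, qualitatively and at the
low-prevalence end quantitatively, the published pattern: the MRI strategy
costs more in every stratum, its incremental cost falls and its incremental
QALYs rise as PSA rises, the ICER decreases strictly across strata, and the
<2.5 ng/mL stratum is not cost-effective at $100,000/QALY.

It does not reproduce the published diseased-side magnitudes (for example
the >10 ng/mL incremental QALY of 0.062, or its $6,000/QALY ICER). Two
structural facts make this impossible from the published inputs alone.
First, any Markov cohort model is linear in its initial state
distribution, and the four strata share one structure differing only in
prevalence and recurrence; expected cost must therefore be an affine
function of those two inputs. The published grid is strongly nonlinear in
prevalence (a per-unit-prevalence cost slope of ≈$49,000 between the two
lowest strata but ≈$3,900 between the two highest). Second, the published
per-diseased-man QALY loss (≈2.1 over ten years) cannot be generated by
the published utility decrements under all-cause mortality alone. Both
point to model content in the original supplementary material (state
diagram and appendix) that the printed tables do not carry. The package
keeps every reconstruction choice explicit and switchable rather than
inventing unpublished parameters, and its acceptance tests record the
resulting deviations rather than masking them.

For the same reason the probabilistic acceptability at $100,000/QALY for
strata ≥2.5 ng/mL computes to ≈40–50% here versus the published 76–81%:
the base-case ICERs sit near the threshold rather than an order of
magnitude below it.

## Probabilistic and deterministic sensitivity analysis

`run_psa()` (or `simulate()` on a fitted model) samples complete parameter
draws — each draw fully determined by `(seed, draw_id)`, so runs are
reproducible and resumable — and evaluates both strategies on common
random parameters. `ceac()` turns the paired outcomes into acceptability
curves on a $0–200,000 grid ($5,000 steps); ties in net monetary benefit
count as not cost-effective. The published analysis uses 10,000 draws;
desk-scale runs of ≥2,000 draws carry binomial error bands of under ±2
percentage points on acceptability fractions and are used in the package's
own tests for runtime reasons (about 10 ms per draw across all strata and
both strategies).

`one_way_sweep()` varies one parameter over its published range (50 points
by default) with everything else at base values; `tornado()` evaluates
interval endpoints and ranks parameters by outcome span. Sweeps at the
base value reproduce the base case exactly, and tornado endpoints equal the
corresponding sweep endpoints — both are tested invariants.

## Microsimulation oracle

`simulate_patient()` / `simulate_cohort()` implement the identical
stochastic process at the individual level, sampling events in the
engine's order and accruing the same rewards. The cohort engine and the
microsimulation are two implementations of one process, so their agreement
is a structural test, not a convergence experiment: at 50,000 patients per
cell all eight strategy-by-stratum base-case cells agree within 3 Monte
Carlo standard errors on both cost and QALYs, and cycle-0 biopsy rates
match the diagnostic cascade's closed form. The microsimulation is also
the package's synthetic-data generator: its trajectories emulate annual
screening histories (states, biopsies, adverse events, detections,
upgrades, recurrences, deaths) with the model's probabilistic structure.
They do not emulate features of real screening data outside that structure
— PSA drift across strata, de-novo incidence during follow-up,
grade-specific test sensitivity, or disease-specific death — so passing
validation shows internal consistency of the two implementations, not
fidelity of the model to an external cohort.

## Numerical choices

* Transition rows are asserted to sum to one within 1e-12 and occupancy to
  be conserved within 1e-10; violations raise errors rather than being
  renormalised silently.
* In the no-disease, no-mortality, no-disutility limit the discounted QALY
  total equals the 10-term annuity 8.786109, used as a closed-form check
  to 1e-5.
* Utility weights floor at zero if sampled decrements stack beyond one
  (cannot occur at base values).
* Distribution fits search the shape parameter on a log grid over
  [1e-4, 1e7] with `stats::optimize`.
* Sampled grade probabilities are renormalised; all other sampled values
  are used as drawn.
* Per-draw seeds are derived as a fixed affine map of `(seed, draw_id)`
  modulo 2^31 − 1, keeping them valid R integers.

## Known limitations

* The published state diagram and appendix were not available; the state
  space is a reconstruction. Every contested choice (false-positive
  handling, adverse-event charging, salvage costing, half-cycle, serial
  composition, screening interval) is a `pca_options()` switch.
* No de-novo cancer incidence during follow-up: the disease pool is the
  entry prevalence, progressing by upgrading.
* No disease-specific mortality, no metastasis or staging states, no
  active-surveillance protocol with scheduled re-biopsy.
* Recurrence is absorbing and carries the post-treatment management cost;
  salvage treatment cost is off by default.
* Costs are payer-perspective 2020 USD; no societal costs.
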