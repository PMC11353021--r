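---
title: "Cumulative effective dose surveillance and lifetime attributable risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative effective dose surveillance and lifetime attributable risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedlar)
```

## The problem

Patients with complex surgical or oncological courses can accumulate many CT
examinations in a short time. Because stochastic radiation risk is assumed
linear in dose at diagnostic levels, the quantity of interest for such
patients is not any single examination's dose but the cumulative effective
dose (CED): the sum of effective doses, in mSv, over all of a patient's
irradiating examinations within a defined time span. A CED of 100 mSv is the
conventional flag for heightened lifetime cancer risk, and dose-monitoring
programmes shortlist patients who reach it. This package implements that
surveillance pipeline end to end for a one-year registry extract of an adult
trauma and emergency CT service, together with the downstream risk
estimation: per-organ cumulative absorbed dose and the BEIR VII lifetime
attributable risk (LAR) of cancer incidence and mortality.

A packaged reference cohort (22 shortlisted patients of an institutional
one-year review, with 4406 adult CT studies in the year and a per-study
recurrent-CT rate of about 5.6%) is used throughout the tests and example
analyses; a synthetic registry generator with known ground truth stands in
for registry extracts that cannot be shipped.

## CED over a sliding window

`compute_ced()` defines the CED as the maximum, over candidate five-year
windows, of the summed effective doses of the patient's non-nuclear-medicine
examinations inside the window. Windows are anchored at examination dates,
which makes the search exact and finite: a maximizing window can always be
slid forward until its right edge touches an examination. Windows are
half-open, `(anchor - window, anchor]`; an examination exactly on the start
boundary is excluded (it anchors its own window), so no examination is
double-counted by adjacent windows. Ties are resolved toward the earliest
window. A window year is 365.25 days; at day granularity the difference from
calendar-year arithmetic is at most one day per window and does not move any
decision in the packaged cohort. The window length is a parameter because
registry practice varies; the default of 5 years matches the surveillance
horizon of the reference cohort.

Nuclear-medicine records are retained in storage but never contribute to a
CED sum; internal dosimetry is out of scope. Radiographs and interventional
procedures do contribute (their doses are small but nonzero).

The implementation uses a sorted two-pointer cumulative-sum pass
(`O(n log n)`); the test suite checks it against an exhaustive
filter-and-sum over all anchored windows on hundreds of randomized
histories.

## The packaged cohort and its expansion

The reference cohort ships as printed per-patient totals: sex, an age range
in integer years, total CED, the average interval between studies, and
CT/X-ray examination counts. Ages printed as ranges are stored as (min, max)
pairs rather than an invented birth date; all band assignments use the upper
end of the range, i.e. the age at the most recent examination, which is the
unique convention reproducing every printed band assignment (including the
79-81-year-old patient banded at 81-90). One entry's examination counts are
internally inconsistent in print (total 61 vs 7 CT + 53 X-ray); the
footnoted extra interventional procedure is kept verbatim and expanded as an
`INTERVENTIONAL` record.

`expand_fixture_history()` reconstructs a per-examination series from the
totals: `n` examinations at a constant spacing equal to the printed average
interval, with 98.8% of the CED apportioned evenly across the CT
examinations and the remainder across the others (the CT share observed for
the cohort's most heavily radiographed patient; general radiography
contributes on the order of one percent of CED in this setting). The last
examination's dose absorbs the floating-point residual so the series sums to
the printed CED exactly. Printed intervals carry one decimal, so exact
reproduction of the mean gap needs sub-day resolution; expanded histories
use fractional `Date` values. Under this expansion the windowed CED
recovers all 22 printed CEDs to within 1e-9 mSv, every printed male band
median exactly, and the shortlist at any threshold matches a direct filter
of the printed table.

## Recurrence

The registry notion of a "recurrent CT" is operationalized per study: a CT
study is recurrent when the same patient has at least one earlier CT study
within the reporting period, so a patient with `m` CTs contributes `m - 1`
recurrent studies. This is the only reading under which a recurrent count
can exceed the number of multiply-scanned patients, as the reference
registry's printed numerator (248 of 4406, 5.6%) requires.
`registry_from_exam_mix()` rebuilds a registry deterministically from
printed per-protocol study and recurrence counts — two studies for each
recurrent count, one for the rest — so the rate arithmetic can be recomputed
rather than copied.

## Organ doses

Per-examination organ absorbed doses come from a declarative coefficient
table keyed by (protocol, sex), in one of two modes: `per_exam` rows are the
organ doses of a typical examination of that protocol, `dlp` rows are
mGy per mGy·cm and are scaled by the examination's dose-length product.
This is the standard desk-scale surrogate for a Monte Carlo dosimetry
engine, which reports organ doses per examination with uncertainty in the
ten-percent range anyway; the packaged default table is calibrated to the
order of magnitude of the cohort's printed per-examination organ doses and
makes no claim of scanner-specific accuracy. Accumulation over a history is
an element-wise sum over the 16-organ set (bladder, red bone marrow, brain,
breast, colon, gonads, liver, lung, esophagus, salivary glands, skin,
stomach, thyroid, kidneys, eye lenses, uterus/prostate), with sex-specific
organs validated against the patient's sex. Non-CT examinations get an
all-zero organ-dose vector with a notice.

`effective_dose()` applies the ICRP tissue-weighted sum E = Σ w_T H_T.
Both the ICRP 103 and ICRP 60 weight sets ship; ICRP 103 is the default.
Organs that the recommendations fold into the remainder carry their share of
the remainder weight, and the eye lens carries zero (it does not enter the
effective-dose sum); consequently the represented weights sum to slightly
less than 1 and a uniform whole-body field is reproduced only up to the
missing remainder organs — a documented property, not an error.

## Lifetime attributable risk

Risk uses the BEIR VII Phase 2 lifetime attributable risk grids: expected
cancer cases (incidence) and deaths (mortality) per 100,000 persons exposed
to 0.1 Gy at a single organ, tabulated by sex, cancer site (bladder, breast,
colon, liver, lung, stomach, thyroid, uterus, prostate) and age at exposure
on the grid 0, 5, ..., 20, 30, ..., 80 years. Coefficients at intermediate
ages are linearly interpolated; ages above 80 clamp to the age-80 value,
since the cohort extends to 81 and extrapolating beyond the published grid
is unjustified. The mortality grid has no thyroid row in its source;
thyroid mortality is stored as zero. Each patient gets one age for risk
(the age at the most recent examination), consistent with the banding
convention.

The per-site risk is coefficient × dose / 100 when doses are in mGy — the
`canonical` convention, since the coefficients are per 0.1 Gy = 100 mGy.
The engine also supports a `per_10mGy` convention, coefficient × dose /
10: back-calculating the reference cohort's printed risk tables (for
example, a female colon risk of 1.41 per 100 patients from a 222.48 mGy
cumulative colon dose at age 59, where the interpolated coefficient is
63.1) shows they are internally consistent only under a per-10-mGy reading,
one decade above the source scale. The convention is therefore explicit
data, not a hidden constant: `canonical` is the default, and selecting
`per_10mGy` emits a message naming the discrepancy. Under the
per-10-mGy reading the engine reproduces the cohort's printed per-site
risks to the printed two decimals for the multi-organ worked cases, and the
printed band totals within a few percent; the printed tables are treated as
plausibility anchors rather than exact targets because of the scale
ambiguity and because the quartile rule behind their IQRs is unstated.

Sites without a dosed organ contribute zero (no imputation), and dosed
organs without a site coefficient in scope (red bone marrow, i.e. leukemia)
contribute nothing to the site-summed total. Totals are per 100,000
internally; the per-100 "%LAR" presentation divides by 1000 at the
reporting boundary.

## Descriptive statistics

`summarize_values()` fixes the presentation conventions: the median of an
even-sized sample is the mean of the two central order statistics (the only
rule reproducing the cohort's printed two- and four-member band medians),
quartiles interpolate linearly between order statistics (`quantile`
type 7), the standard deviation uses `n - 1`, and a singleton reports its
value with an absent SD. Because the quartile rule behind the printed IQRs
is unstated, IQR cells are checked for plausibility (ordering, bracketing)
but not asserted exactly. Empty strata are emitted as explicit NA rows, as
in the printed tables. Percentage shares are rounded to one decimal and are
allowed to miss 100 by up to 0.3 from rounding.

## The synthetic registry generator

`simulate_registry()` emulates the statistical structure of the one-year
registry so that every pipeline stage can be tested with known ground
truth:

* **Protocol mix** — the service's observed one-year proportions over the
  seven named protocols (largest share 32.6%).
* **Per-examination effective dose** — log-normal per protocol,
  right-skewed and strictly positive, with plausible medians of 7-25 mSv
  and a geometric SD of 1.6. The reference registry publishes no per-exam
  dose distributions; these defaults are assumptions, stated here once, and
  are not tuned thereafter.
* **Per-patient CT count** — zero-truncated negative binomial plus an
  explicit high-recurrence subpopulation (fraction 0.005, mean 8 CTs,
  size 3). The base mean 0.016 with size 0.5 gives a zero-truncated mean of
  about 1.025, so the overall expected count is about 1.059 CTs per patient
  and the expected per-study recurrence rate (E[k] - 1)/E[k] is about 5.6%,
  matching the registry condition, while the subpopulation supplies the
  heavy tail of multiply-scanned patients that produces a realistic handful
  of 100 mSv exceedances per four thousand patients. Year-to-year (seed-to-
  seed) variation of the realized rate is wide — a few hundred recurrent
  studies hinge on ~20 heavy patients — which mirrors the instability such
  small tails have in practice.
* **Episode structure** — each patient's examinations fall in one episode
  (default 180 days) far shorter than the CED window, so the ground-truth
  CED is the plain sum of that patient's generated doses; this is what
  makes exact pipeline-recovery assertions possible.
* **X-ray attachment** — Poisson-attached radiographs at 2 per CT with
  ~0.05 mSv doses, matching the cohort's roughly 2:1 radiograph:CT ratio.
* **Ages and sex** — truncated normal ages on [18, 90] (mean 48, SD 18) and
  a 68% male share, as in the service's registry.

Generation is vectorized, bit-reproducible given a seed, and runs on a
private RNG stream that leaves the caller's random state untouched.
`simulate_shortlist_experiment()` pairs the simulated exceedance fraction
with a closed-form expectation for the configurations that admit one (fixed
counts with degenerate doses; single-CT log-normal mixtures) and refuses
others loudly, so Monte Carlo coverage checks never silently compare a
simulation to itself.

What the generator does **not** emulate: correlated protocol sequences per
diagnosis, multi-episode histories spanning window boundaries, scanner or
facility effects, and pediatric patients. Passing recovery tests therefore
show the pipeline's arithmetic is right under the stated statistical
structure, not that the structure captures any particular institution.

## Numerical choices

* Window years are 365.25 days; windows are half-open at the start; ties
  break to the earliest window.
* Fixture expansion corrects the last dose so sums match printed CEDs
  exactly; comparisons in tests use 1e-9 mSv (sums) and 1e-6 days
  (intervals).
* Interpolation clamps above the last grid age and errors below age 0 or
  for sex-invalid sites.
* Degenerate inputs fail loudly: empty histories, zero CT denominators,
  single-examination intervals, organs without weights, female organs in
  male vectors.
* The analyses in `analysis/` and the acceptance script run the full
  pipeline at the reference sizes (22 histories, a 4406-study registry,
  20 × 10,000-patient simulations), chosen to match the cohort they
  reproduce while keeping a complete run in the tens of seconds.

## Known limitations

* Organ-dose coefficients are per-protocol typical values; no patient-size
  scaling, tube-current modulation or scanner spectra. Accuracy is
  order-of-magnitude by design.
* Leukemia (red bone marrow) and "other solid" risks are out of scope; the
  site-summed LAR therefore understates the all-cancer LAR.
* LAR point estimates only; the BEIR VII uncertainty machinery (ERR/EAR
  weighting, DDREF, survival-table integration) is not reimplemented.
* The dose-scaling ambiguity of the reference risk tables is surfaced, not
  resolved; downstream users must choose a convention knowingly.
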