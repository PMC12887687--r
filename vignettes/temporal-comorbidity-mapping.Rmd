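---
title: "Temporal comorbidity mapping for dementia subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal comorbidity mapping for dementia subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

comorbmap builds temporal comorbidity profiles for Alzheimer's disease (AD)
and vascular dementia (VaD) from longitudinal, first-instance ICD-10
inpatient records, spanning twenty years before to ten years after the
dementia diagnosis. This vignette is the package's account of the methods:
what each analysis layer assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open.

## Input model

Two tables drive everything: a participants table (`id`, `sex`,
`birth_year`, `death_date`) and a diagnoses table (`id`, `icd10_code`,
`date`). The diagnosis stream is assumed to be *first-instance only*: one
row per (participant, code), dated at the earliest inpatient occurrence.
The readers enforce this by deduplicating to the earliest date per pair, so
repeat admissions never inflate counts. Codes are stored dotless and
uppercase (`F001`); dotted and lower-case dialects are accepted on input.
Only the year of birth is available, so all ages are computed from July 1
of the birth year; age differences are consequently near-integers, which
matters when choosing the matching tolerance (below).

Diagnoses are assumed permanent once recorded: a condition observed at any
time remains "present" in every later window. This is the standard
cumulative-burden reading of hospital codes; it cannot distinguish acute
from chronic disease and therefore overstates the persistence of, for
example, an isolated pneumonia.

## Diagnosis resolution

Participants often carry codes from several dementia subtype categories
(AD: F00\*, G30\*; VaD: F01\*; other: F02\*, G31; unspecified: F03; mild
cognitive impairment: F067). The resolver:

1. excludes anyone with a Down-syndrome code (Q90 family) anywhere;
2. excludes anyone with four or more distinct subtype categories;
3. otherwise takes the most common category; a category tie is broken by
   the earliest-dated code among the tied categories, then by the fixed
   precedence AD > VaD > other > unspecified > MCI;
4. labels the participant AD or VaD if that category wins, with the index
   date set to the earliest date of any code in the winning category;
   a winner among other/unspecified/MCI is excluded.

Delirium (F05 family) is never a dementia category, so it cannot drive the
primary diagnosis, but its events are retained as comorbidities throughout.

Two points here were open design. The tie rule is not fully determined by
the source methodology (the original workflow involved clinician review);
earliest-first mirrors the clinical intuition that the first recorded
subtype diagnosis is the most informative, and the precedence order only
matters for exact date ties. Second, when the most common category is
other/unspecified/MCI but AD or VaD codes are also present, we exclude: the
participant's dominant coding does not support a specific subtype label.
Both rules are enforced identically by an independent brute-force oracle in
the test suite (1,000 random event lists, exact agreement).

## Matching and index dates

Each AD and VaD case is matched 1:1 without replacement to a control with
no dementia-category code anywhere in their records, of the same sex, whose
age at the case's diagnosis date differs by at most 1 year (the default
`tolerance_years`; with birth-year-resolution ages the effective choices
are "same birth year" and "adjacent birth year"). The matched control
inherits the case's diagnosis date as a *placeholder flag date*, making all
temporal quantities comparable across arms.

Cases are processed in order of matching difficulty (fewest eligible
candidates first) with greedy nearest-age selection and seeded random tie
breaking, so matching is deterministic given a seed. A control must be
alive on its placeholder date: dementia cases necessarily survive to
diagnosis, and allowing already-deceased controls would truncate the
control arm's observation and manufacture spurious prevalence differences
(an immortal-time artifact we observed directly in early null simulations
of the full cohort pipeline).

The control-disease cohort is built the same way for hip fracture (S72
family; earliest fracture date as index), excluding anyone with a dementia
code, with its own matched controls.

## Time windows and presence matrices

Offsets are signed years, `(event date - index date) / 365.25`. The seven
pre-diagnosis windows partition all time before the index — 20+ years
before, 15-20, 10-15, 7-10, 5-7, 2-5, and 0-2 years before — and five
cumulative post windows anchored at the index cover (0, 2] through (0, 10]
years after. Window "a to b before" covers offsets in (-b, -a]; "20+
before" is open-ended below. Post windows are nested by design, reflecting
the cumulative burden perspective. Events beyond ten years post-index are
retained in the raw data but fall outside every window.

An offset of exactly zero (comorbidity codes recorded on the diagnosis
admission itself) is assigned to the "0-2 before" window by default:
same-admission codes describe the burden the patient brought to the
diagnosis. The alternative (counting them as post-diagnosis) is available
via `default_windows(diagnosis_day_pre = FALSE)`.

A presence matrix codes each (participant, condition) cell per window as
absent, present, or new: *new* when the condition's first instance falls
inside the window; *present* when it fell in any earlier window
(cumulative carry-forward). At block level the condition is the WHO ICD-10
(2019) block; a block's first instance is its first member code, and the
per-block sum of distinct present codes is emitted alongside the binary
indicator. Four-character codes inherit the block and chapter of their
three-character prefix. The block and chapter table ships as a plain-text
TSV (`inst/extdata/icd10_blocks.tsv`).

Codes that define a cohort are not comorbidities of that cohort: dementia
subtype codes, and the S72 family when a hip-fracture analysis is
configured, are excluded from the comorbidity event stream.

## Prevalence testing

Between-arm prevalence differences use the two-sided Mann-Whitney U test on
binary presence indicators (code level) or per-block sums (block level),
exactly as a nonparametric two-sample comparison — on binary data this is
equivalent to a proportion test, and it is implemented as stated rather
than replaced, for fidelity. The U statistic uses midranks; p-values come
from an exact permutation distribution (a dynamic program over doubled
midranks, valid under arbitrary ties) when `n*m <= 200` and from the
tie-corrected normal approximation with continuity correction otherwise.
Code-level matrices go through a vectorized closed-form equivalent of the
same test for speed; the test suite asserts exact agreement between the
two paths and against `stats::wilcox.test` and a combinatorial enumerator.

Bonferroni correction is applied across the family of dementia-vs-control
comparisons, with the family size defaulting to the number of conditions
tested at that level (code and block families are corrected separately;
an explicit `m` can be supplied). Conditions below a pooled prevalence
floor (default 0.5%) are excluded as vacuous — the source methodology
states no floor, and 0.5% keeps every test at least minimally informative
at the cohort sizes used here. PRS group comparisons (AD-control,
VaD-control, AD-VaD) use the same test with Benjamini-Hochberg correction
across the three pairs.

The pipeline runs the comparison twice: dementia overall vs all matched
controls (the headline ranking at both code and block level) and each
subtype against its own matched controls. The subtype-specific significant
sets feed that subtype's regression models and annotate its characteristic
conditions — pooling AD and VaD dilutes subtype-specific signals (a
VaD-only enrichment is only a third of the pooled arm).

## Co-occurrence networks and characteristic conditions

Per window and cohort, an undirected network has a node for every
condition with cumulative prevalence at or above `min_node_prev` (default
1%) and an edge between two conditions when the number of participants
with both present reaches `min_edge_count` (default `max(5, 0.5%
of the cohort)`). Edge weights are raw co-occurrence counts with support
fractions; a phi-coefficient edge rule is available behind a config flag.
Degree centrality is `degree / (|V| - 1)`, with scores in [0.5, 1]
conventionally read as "central". The exact edge definition used in the
source analysis is not public; the count-threshold rule was chosen as the
simplest auditable definition sufficient for the characteristic-set logic.

A condition is *characteristic* of a subtype in a window when it is a node
of the subtype's network but not of the matched-control network built with
identical thresholds. "Absent from controls" is therefore
threshold-relative, not literally zero prevalence — literal zero is
unstable at these cohort sizes. The chronologically first such window
gives the condition status "new"; later windows "re-occurring". Conditions
that are also characteristic of the hip-fracture cohort (vs its own
controls, in any window) are flagged `validated = FALSE` rather than
deleted, so outputs can display both.

A consequence worth knowing: a condition whose cumulative prevalence
crosses the node floor *during* the window sequence sits near the
threshold in the crossing windows, and its node membership there is
effectively a coin flip in both arms. Isolated characteristic flags in
such windows are expected noise; the planted-recovery tests quantify this
(false-flag rate at or below 5% under the test conditions below).

The optional Bayesian-network learner is a documented standard variant —
greedy hill climbing over edge additions, deletions, and reversals,
scoring binary conditional probability tables by BIC, with at most three
parents per node and seeded restarts — not a reproduction of the source
supplement's (unpublished) algorithm. With ~2,000 rows it reliably
recovers a strong chain's skeleton and stays empty on independent columns;
its BIC penalty `log(n)/2` per parameter makes edges at very small n
essentially unreachable unless dependence is near-deterministic.

## Regression and survival

Per pre-diagnosis window and subtype, one multivariable logistic model
regresses case-vs-matched-control on the window's condition indicators
(restricted to the subtype's Mann-Whitney-significant set) plus age, age
squared, sex, and an age-by-sex interaction. Odds ratios are
`exp(coefficient)` with Wald 95% intervals — Wald rather than profile
likelihood to match standard forest-plot reporting; ORs above 3 carry a
display-cap flag. Complete separation is detected (diverging estimate or
exploding standard error), flagged, and excluded from the significant set;
exactly collinear condition columns abort with their names. The source
description of the model covariates is followed where its two statements
disagree ("age, age squared, and an age-by-sex interaction" vs "adjusted
for sex, age, and death date"): a death-date adjustment is ill-defined for
a logistic outcome and is not implemented.

Model discrimination is summarized by AUROC — computed by midranks, so it
equals U/(n1·n0) on the same scores — under stratified 5-fold
cross-validation (the source does not state its validation split; held-out
evaluation is the conservative choice). L1/L2-regularized fits of the same
design are available as comparison models, reported without intervals.

Survival uses a Cox proportional hazards model with time from index date
to death or administrative censoring (default 2024-04-30, the mortality
cutoff the generator emulates), event = death, Breslow tie handling, and
covariates group, age at index, and sex.

## The synthetic-data generator

The generator stands in for access-restricted inpatient extracts. Per
participant: sex is a fair coin; birth year is uniform on 1936-1945;
observation runs from age 40 to the censor date. Cases draw a scheduled
diagnosis age from a truncated normal — default N(75, 5) on [62, 86],
always at least a year before censoring — and receive one (sometimes two)
of their subtype's codes at that date, plus occasionally an
unspecified-dementia code afterwards, so the resolution workflow has real
work to do. Hip-fracture participants receive an S720 code at an index age
drawn from N(77, 6) on [60, 92] — fractures cluster later in life than
this cohort's dementia diagnoses.

Conditions occur in discrete annual steps: each year, every
not-yet-diagnosed catalog condition occurs with probability
`p60 * exp(slope * (age - 60))` (capped at 0.5), where `p60` is the annual
first-admission probability at age 60 and `slope` the log-linear age
trend. Discrete years rather than continuous hazards keep the expectation
arithmetic exact for calibration tests. Planted effects multiply the
*odds* of occurrence in every year whose offset from the scheduled
diagnosis falls in the planted window, so a planted multiplier is directly
comparable to a recovered window odds ratio. Death follows the same
annual-step scheme (default 0.4% at 60, doubling every eight years,
multiplied four-fold after the index); cases are conditioned to survive to
their diagnosis. Only first instances are recorded; no event precedes age
40 or postdates death or the censor date. A per-participant PRS is
Gaussian with configurable group shifts (+0.5 SD AD, +0.25 SD VaD).

The default catalog lists ~60 real ICD-10 conditions with rates chosen to
be plausible for first inpatient admissions in an older UK cohort;
`synthetic_catalog()` appends arbitrary numbers of filler codes for
large-family simulations. What the generator deliberately does *not*
emulate: "dump events" (many codes on one admission date), coding-practice
drift over calendar time, ethnicity structure, primary-care records, and
any extra all-cause health-care contact burden in cases beyond the planted
effects. Consequently a passing pipeline run demonstrates that the
analysis recovers *planted* temporal structure at realistic scales — not
that real dementia cohorts look like this. In particular, because cases
and controls share the baseline condition process, the full-horizon
prevalence comparison can show mildly *lower* cumulative prevalence of
common conditions in cases: cases die faster after the index, so their
post-index observation is shorter. Real cohorts show the opposite
direction because dementia patients genuinely accumulate more codes.

### Fixtures and study conditions

`make_fixture()` provides three named bundles. `tiny` is twenty hand-built
participants whose expected labels are documented in the tests. `null`
plants nothing. `planted-AD-VaD` (2,000 AD / 1,000 VaD / 6,000 background
/ 2,000 fracture; diagnosis age N(70, 4) on [60, 80]) plants two kinds of
truth: *persistent* multi-window enrichments of narrative codes
(depressive episodes from 20 years before AD onwards, food/fluid-intake
symptoms approaching AD, cerebral infarction and type 1 diabetes before
VaD, pressure ulcers and pneumonia after diagnosis in both subtypes),
which surface in the Mann-Whitney and regression layers; and
*single-window* enrichments of two rare codes (intestinal malabsorption
10-15 years before AD, other cerebrovascular disease 10-15 years before
VaD), which surface as window-specific characteristic conditions in the
network layer. The diagnosis-age distribution was set so the earliest
windows fall inside the age-40+ observation span; the rare codes' baseline
rates keep their control-arm window prevalence below the 1% node floor
while the planted arm clears it — both choices made by expectation
arithmetic before the recovery tests were written, and then frozen.

The heavier validity checks use purpose-built conditions at the sizes they
state: the null family-wise-error check runs 200 replicates of ~500
conditions at 1,000 per arm with mortality switched off (the exact null of
the testing layer); network planted recovery runs 50 replicates at 2,000
per arm with a constant-rate marker condition and diagnosis age N(60, 2),
placing the planted window at the start of observation so the in-window
enrichment dominates cumulative prevalence; regression calibration uses
300 direct logistic simulations across odds ratios 1.5, 2, and 3; survival
calibration uses 100 exponential simulations at hazard ratio 2. The
single-run end-to-end demonstration uses the `planted-AD-VaD` fixture
above.

## Numerical choices and degenerate inputs

* Offsets divide by 365.25; boundary membership is half-open as stated
  above, so every pre-index event lands in exactly one pre window (an
  exhaustive 0.01-year sweep asserts this).
* All-equal Mann-Whitney input returns p = 1; zero-variance prevalence
  columns are flagged `degenerate` and never significant.
* Empty presence matrices yield empty networks with a warning; a network
  with fewer than two nodes has all centralities 0.
* Matching with an exhausted stratum reports the unmatched cases and
  continues; an empty control-disease cohort skips validation downstream
  with a logged reason.
* The Cox layer drops non-positive follow-up times, errors on zero events,
  and warns when a whole group is censored.
* Pipelines and the generator are deterministic given a seed; the
  reproducibility test asserts identical bundles across repeated runs.

## Known limitations

Beyond the generator's simplifications listed above: the characteristic
set is threshold-relative and noisy near the node floor; block-level
Bonferroni and code-level Bonferroni are separate families (the exact
family used in the source is not stated); the matching tolerance interacts
with birth-year-resolution ages; and the Bayesian-network learner is a
stand-in variant. Analyses are correlational throughout — nothing here
distinguishes early risk markers from causal contributors.
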