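---
title: "Methods: off-label classification and prevalence of paediatric respiratory prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-label classification and prevalence of paediatric respiratory prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offlabelr)
```

## The problem

Respiratory drugs — beta-2-agonists, muscarinic antagonists, inhaled
corticosteroids, leukotriene antagonists — are among the most commonly
prescribed drug classes in children, yet most of their regulatory labels
(Summaries of Product Characteristics, SPCs) approve them only for asthma
or COPD and only from a particular age onwards. Prescribing outside the
label, to younger children or for unapproved diagnoses such as acute
bronchitis or upper respiratory tract infections, is common and clinically
contested. Quantifying it from ambulatory claims data requires three
ingredients this package provides:

1. a **label knowledge base** giving, per ATC code, the approved minimum
   age and approved indications expressed as ICD-10 code prefixes;
2. a **per-prescription classifier** that joins prescriptions to the
   diagnoses documented for the same child in the same billing period and
   assigns one of five statuses: on-label, off-label by age, off-label by
   indication, off-label by age *and* indication, or indeterminate;
3. **period prevalence rates** (PPRs): distinct children with at least one
   prescription of a drug in a year, over the year-end population
   corrected for the insured share, per 10,000 children.

Because the claims database that motivates this design is not publicly
available, the package ships a synthetic claims generator with known
ground truth; all statistical validation runs against it, and the
arithmetic of the published reference tables is checked exactly from the
printed counts (`reference_checks()`).

## The label knowledge base and its resolution rules

The shipped KB (`default_label_kb()`) covers the 24 compounds of ATC group
R03 analysed by the pipeline, one record per (ATC code, SPC snapshot year
2004/2008). Two resolution rules turn several records for one compound
into the *effective label* used by the classifier:

* **lowest age restriction** — `min_age_years` is the minimum across
  records (a record value of 0 encodes "no restriction");
* **widest indication set** — the union of the records' indication
  prefixes.

Both rules are deliberately conservative: a prescription is counted
off-label only if it falls outside *every* version of the label, so the
classifier under- rather than over-states off-label use when labels
differ across devices or years.

SPC indications are prose; the KB maps them to ICD-10-GM block prefixes:
asthma → J45, J46; COPD and chronic obstructive bronchitis → J44;
pulmonary emphysema → J43; chronic bronchitis → J41, J42; acute
bronchitis → J20; "obstructive respiratory diseases" → J43–J46;
"respiratory diseases requiring ICS" → J41–J46. No authoritative
SPC-to-ICD code list exists, and different reasonable mappings shift
off-label counts; the mapping therefore lives in an editable CSV asset
(`inst/extdata/label_kb.csv`), not in code. Matching is by normalized
prefix (uppercase, dot stripped), because SPC indications are block-level
concepts while claims carry terminal codes of varying digit depth.

## The classifier

For each prescription, with `a` the child's age in completed years at the
dispense date and `D` the set of ICD-10 codes documented for the child in
the linkage window:

* `age_ok`: `a >= min_age_years`;
* `ind_ok`: **any** code in `D` matches the effective indication
  prefixes. Any-match is the standard utilisation-study convention and
  continues the "widest label" logic: off-label by indication means *all*
  documented diagnoses are unapproved.

The four combinations give the status; `D = ∅` is governed by the
missing-diagnosis policy. The default, `indeterminate`, reports such
prescriptions in their own column rather than forcing them into either
side; `on_label` and `off_label_indication` are provided as sensitivity
bounds, since how the original analysis treated them in its summary table
is not knowable (its indication breakdown explicitly excluded them).

**Diagnosis linkage.** German ambulatory claims document diagnoses per
calendar quarter, not per encounter, so the default window links a
prescription to all codes of the same patient-quarter
(`same_quarter`); `same_year` is offered for sensitivity analysis. A
consequence worth knowing: two prescriptions of one patient in the same
quarter share linked codes, so classifications are not independent across
prescriptions. In validation scenarios that compare the classified
off-label share against a known per-prescription probability, we keep the
per-quarter prescription rate low (≈1% co-quarter probability) so this
sharing perturbs the estimate by well under the binomial tolerance.

**Two age conventions.** Label checks use age at the dispense date (the
event-accurate reading of an age restriction). Prevalence strata use age
at December 31 of the analysis year, matching the year-end population
denominator; the prevalence population is accordingly defined by year-end
age ≤ 18, so a child dispensed at 18 who turns 19 before year end counts
in the off-label tables but not in the PPR. This keeps stratified
numerators exactly conservative (they sum to the unstratified numerator)
and every stratum matched to a denominator row.

## Aggregation and reporting

`summarize_offlabel()` tabulates per compound, compound class, or in
total: all prescriptions, off-label overall (the sum of the three
off-label types — a partition identity asserted by the tests on every
row), the percentage off-label, and the indeterminate count.
`breakdown_offlabel_indications()` reports, among prescriptions off-label
by indication or by age&indication, the non-approved codes by category
with **multiple counting** — each off-label code on each prescription
increments its category, so percentages can sum above 100. The category
map follows ICD-10 block headings (J00–J06 acute upper respiratory
infections, J20 acute bronchitis, J21–J22, J30–J39, J40 bronchitis nec,
J43–J44, then a catch-all J prefix for other respiratory diseases);
matching is first-match-wins over ordered rows, and the loader rejects
maps in which an earlier row makes a later one unreachable. Reporting
options `top_k` (default 3) and `min_n` (default 5,000 prescriptions)
mirror the published table's restrictions.

Percentages are held at full precision internally and rounded
half-away-from-zero to one decimal (`format_pct()`) only for display and
for the exact reference checks — base R's round-half-even would disagree
with the printed tables at ties.

## Period prevalence rates

For drug *d*, year *y*, stratum *s*:

PPR = scale × (distinct children with ≥1 prescription of *d* in *y* and
stratum *s*) / (population of *s* on Dec 31 of *y* × coverage fraction)

with scale 10,000 and coverage 0.85 by default (85% of the paediatric
population is statutorily insured; the correction is applied uniformly
across ages and genders, as the published analysis assumed equal
distributions in statutory and private insurance). Numerators count each
child once per (drug, year) however many prescriptions they fill, and a
child treated in two years counts in both — period prevalence, not
incidence. Drugs enter the analysis only with a final-year PPR of at
least 0.1 per 10,000 (inclusive bound). Trends are reported as absolute
change, percentage change, and fold change (the published idiom mixes
"−97%" with "39-fold"); a zero baseline flags the relative measures as
not applicable rather than producing infinities.

## The synthetic generator

`simulation_scenario()` defines, per drug: an annual prescription rate
per child (prescription counts are Poisson per patient-year), a diagnosis
mixture over ICD-10 codes, and a missing-diagnosis probability; mixture +
missing probabilities must sum to 1. Each prescription draws one
component: an ICD code becomes a diagnosis event in the dispense quarter,
the missing component leaves the prescription undiagnosed. An optional
second independent draw (`p_second_dx`) produces co-diagnoses to exercise
multiple counting. The component that fired is stored in a sidecar truth
table, which the tests use for parameter recovery. The default panel of
four drugs spans the rule space (no restriction/broad, age-restricted,
adult-only/narrow, oral fixed combination) at rates of the magnitude
implied by prevalences of a few hundred per 10,000 children.

The population is a closed cohort: ages are sampled uniformly (by
default) for the first study year and advance with the calendar, and the
year-end population table is derived from the realized counts divided by
the coverage fraction, so PPR denominators are internally consistent.
What the generator does **not** emulate: seasonality of respiratory
infections, comorbidity and prescriber correlation, in-/out-migration,
device-level labelling, and the true Bavarian prescribing rates (never
published as raw counts). Passing tests therefore demonstrate the
correctness of the pipeline's arithmetic and rules under known
mechanisms, not calibration to any real population.

All randomness flows from one master seed (per-stage child seeds by fixed
offset), making every dataset, classification and output table
byte-identical across runs and platforms.

## Validation design and problem sizes

* **Exact desk checks** — every percentage, partition sum and trend delta
  of the published reference tables recomputed from the printed counts
  (100 checks, `reference_checks()`), at one-decimal rounding.
* **Oracle equivalence** — on 100 random datasets of 20–120
  prescriptions with adversarial codes (case/dot variants, non-ICD
  strings, non-respiratory codes), the vectorised classifier and
  aggregation equal a deliberately naive one-prescription-at-a-time
  re-implementation, exactly.
* **Parameter recovery** — a single-drug scenario with off-label
  diagnosis probability 0.30, no age violations and no missing diagnoses
  (250,000 children × 5 years at rate 0.04 ≈ 46,000 prescriptions after
  the age filter) recovers the off-label-by-indication share within 3
  binomial standard errors; an all-on-label scenario yields exactly zero.
* **Invariants** — partition identity on every summary row; monotonicity
  (dropping age floors converts age-related statuses exactly; widening
  indication sets never increases off-label counts); stratified-numerator
  conservation for PPRs; determinism under a fixed seed.

These sizes were chosen to give the binomial checks comfortable power
while keeping the full suite near a minute of runtime.

## Known limitations

* The SPC-to-ICD mapping is an explicit modelling choice; real analyses
  should review `inst/extdata/label_kb.csv` against current SPC wording.
* Quarter-level linkage cannot say *which* diagnosis motivated a
  prescription; the any-match rule is a lower bound on indication-related
  off-label use, and co-quarter prescriptions share evidence.
* Off-label rates are per prescription, not per child; dose- or
  device-level off-label use is out of scope.
* The generator's closed aging cohort under-represents the youngest ages
  in later study years, visible in the demo outputs as declining totals —
  a property of the emulation, not of the method.
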