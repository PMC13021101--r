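---
title: "Computable HLH phenotypes from EHR extracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computable HLH phenotypes from EHR extracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlhphenotype)
library(dplyr)
```

## The problem

Hemophagocytic lymphohistiocytosis (HLH) is a rare, often fatal
hyperinflammatory syndrome. Clinically it is diagnosed through the
HLH-2004 framework: a molecular finding, or at least **5 of 8** clinical
criteria — fever, splenomegaly, cytopenia of ≥2 blood lineages,
hypertriglyceridemia and/or hypofibrinogenemia, tissue
hemophagocytosis, low natural-killer-cell activity, ferritin ≥500 µg/L,
and soluble CD25 ≥2400 U/mL. None of these is recorded in an electronic
health record (EHR) as a single field: they hide in laboratory tables,
vital-sign flowsheets, pathology reports and free-text notes, while the
administrative signals a researcher might reach for first — ICD-10
diagnosis codes and named treatment plans — capture overlapping but
distinct populations.

This package implements three *computable phenotypes* — machine-evaluable
cohort definitions — over a tabular EHR extract:

1. **Coding phenotype** — any in-window ICD-10 code D76.1 or D76.2.
2. **Treatment-plan phenotype** — any treatment plan or protocol whose
   display name contains "HLH" or "h(a)emophagocytosis".
3. **Clinical-criteria phenotype** — at least 5 of the 8 operationalized
   HLH-2004 criteria met within a single hospital episode.

Downstream, the package compares patients in the criteria cohort who
received HLH-directed therapy with those who did not, and summarises a
screening cohort of all encounters with both high ferritin and fever.

## Operationalizing the criteria

Criteria are evaluated over an **episode**: the admission-to-discharge
interval of an encounter. A criterion is met if it occurs at *any point*
during the episode. Five criteria come from the laboratory table, one
from the temperature flowsheet and two from free text.

| Criterion | Rule | Default |
|---|---|---|
| Ferritin | value ≥ threshold (inclusive) | 500 µg/L |
| Cytopenia | ≥2 lineages low: Hgb < 90 g/L (<100 g/L if under 28 days old at collection), platelets < 100×10⁹/L, neutrophils < 1.0×10⁹/L (all strict `<`) | — |
| TG / fibrinogen | triglycerides ≥ 3.0 mmol/L or fibrinogen ≤ 1.5 g/L (both inclusive) | — |
| sCD25 | value ≥ 2400 U/mL (inclusive) | — |
| NK activity | abnormal-low flag per local laboratory reference | 0/1 flag |
| Fever | one oral reading ≥ 38.3 °C, **or** a consecutive run of oral readings all ≥ 38.0 °C spanning ≥ 60 minutes | — |
| Splenomegaly | non-negated note mention of a lexicon term | see below |
| Hemophagocytosis | pathology pattern match, negation-filtered, with manual adjudication override | see below |

A laboratory test that was never performed in the episode is *not
abnormal*: the flag is `FALSE`. Because that convention erases the
distinction between "tested normal" and "never tested", every profile
carries a parallel `measured_*` column, and report rows for sparsely
ordered tests (sCD25, NK activity) are emitted with both denominators.

Conventions adopted where the rules leave room (each is a deliberate
package decision):

* **Fever run span.** The sustained clause uses the first-to-last
  timestamp span of a maximal run of ≥38.0 °C oral readings with no
  intervening sub-38.0 oral reading. No interpolation is attempted, so a
  single reading can never satisfy the clause — a span needs two
  timepoints.
* **Cytopenia simultaneity.** Lineages are assessed over the whole
  episode independently (consistent with "met at any point"); a stricter
  same-calendar-day reading is available as the config toggle
  `strict_cytopenia_same_day` (default off).
* **Triglyceride fasting status** is not recorded in extracts; any value
  is used.
* **Infant age** is computed at sample collection, cutoff 28 days,
  exclusive.
* **Episode scoping.** Laboratory, temperature, note and pathology rows
  are tied to an episode by `encounter_id`, the link the extract itself
  supplies. Medications are scoped by administration *time* falling in
  the index episode window, since therapy may be ordered under a
  different administrative encounter. Open-ended inpatient encounters
  truncate at the study window end; outpatient encounters with no end
  are same-day episodes.

## Text phenotyping

Splenomegaly is detected by scanning notes for the lexicon
`splenomegaly`, `big spleen`, `organomegaly`, `enlarged spleen`, and
discarding mentions negated by `no`, `none`, `absence`, `without`, or
`negative` occurring within **3 words before** the term. The package
fixes the parts the prose rule leaves open:

* a *word* is a maximal alphanumeric run (punctuation separates, case is
  folded);
* the window is counted in tokens up to the **first** token of a
  multi-word term;
* sentence boundaries are ignored — a cue within 3 tokens negates even
  across a period. This is a convention, not a claim about clinical
  language; the window is deliberately tiny, which bounds the damage.
* matches are non-overlapping left-to-right, longest phrase first; a
  note is positive if **any** mention survives negation, so an affirmed
  mention later in a note outweighs an earlier negated one.

Hemophagocytosis search uses the patterns
`h(a)emophagocytosis` / `h(a)emophagocytic` over pathology reports. The
original workflow resolved matches by manual chart review; a fully
automated pipeline cannot, so the package applies the same negation rule
as a stand-in and honours a per-report `adjudicated_positive` override
wherever chart-reviewed labels exist. No general clinical NLP
(uncertainty, experiencer, section logic) is attempted.

## Cohorts, index encounters, overlap

For the criteria phenotype, each patient's **HLH-specific (index)
encounter** is the in-window encounter with the maximum criteria count;
ties go to the earliest episode start, then the encounter identifier, so
membership is invariant to row enumeration order. Membership requires
the maximum count to reach `criteria_required` (default 5; configurable
to support sensitivity analyses and the screening stratification).

Coding and plan events are indexed at the *first* qualifying event. When
such an event carries no encounter link, the package resolves it to the
in-window encounter containing its timestamp, else the nearest
subsequent encounter, else none — this keeps encounter-scoped therapy
queries well defined for every cohort.

ICD matching is exact on the upper-cased, trimmed code (child codes do
not match); plan matching is a case-insensitive substring test on both
display and protocol names; both event streams are restricted to the
study window (June 2, 2018 – May 31, 2025 by default).

`compute_overlap()` reports the seven regions of the three-set Venn
diagram plus the union, and the regions are tested to reconcile with
per-patient set algebra.

## Therapy, outcomes, statistics

**HLH-directed therapy** is receipt of any dose of dexamethasone,
methylprednisolone, anakinra, ruxolitinib, cyclosporine, etoposide or
emapalumab. Exposure is classified both within the index episode window
and anywhere in the study window; the index-episode drug set also yields
a pattern (`steroid_only`, `steroid_plus_other`, `other_only`, `none`),
with "steroid" meaning the two corticosteroids on the list.

Outcome conventions: the 30-day mortality window is anchored at the
index episode **start**, boundary inclusive; in-hospital death is a
death date inside the episode or an explicit `discharged_alive = FALSE`;
stem-cell transplant is any transplant dated after the index start; the
ICD-timing variable compares the first HLH code date to the index
interval (`before`/`during`/`after`/`never`).

Statistics follow the conventions of a descriptive two-group clinical
comparison:

* Wilcoxon rank-sum (normal approximation, tie-corrected) for continuous
  rows; for categorical rows, Fisher's exact test when a 2×2 table has
  any expected cell below 5, otherwise chi-square with continuity
  correction (k×2 tables always use chi-square). The expected-cell rule
  is the standard convention; it is stated here because nothing in the
  underlying report format pins it down.
* **Risk differences are computed round-first**: group rates are rounded
  to one decimal percentage point and then subtracted, which is how
  printed clinical tables are differenced (15.0 − 13.5 = 1.5). The
  unrounded difference and a Wald 95% interval on it are always emitted
  alongside.
* The median length-of-stay difference carries a **seeded percentile
  bootstrap** interval (2000 resamples within each group, default);
  the method is a package choice since none is implied by a difference
  of printed medians.
* Degenerate tables (a zero margin) report `NA` with method
  "not applicable" rather than a fabricated p-value.

The screening summary tabulates, among all encounters meeting both the
ferritin and fever criteria, the prevalence of the six remaining
criteria for all encounters and for the strata at/below the criteria
threshold, plus the threshold stratum's share and the number needed to
screen, `round(total / n_meeting)`. (Published descriptions of this
stratification alternate between ">5" and "at least 5" criteria; the
package reads both as ≥5, matching the stated diagnostic rule.)

## The synthetic generator

`simulate_ehr()` exists so that every stage of the pipeline is testable
without patient data. It is a *stylized latent-state Bernoulli mixture*,
not a mechanistic disease model: each patient carries a latent
hyperinflammatory state (default prevalence 5%); the latent state
switches each criterion's test-ordering and threshold-exceedance
probabilities between a positive and a background regime in one
designated flare encounter; the realized criteria count drives treatment
through a monotone probability map; treatment and latency drive plan
application, ICD coding, ICU stay, log-normal length of stay (medians
around 30 vs 18 days) and death. Notes are realized from affirmed,
negated or neutral templates, and the template identity is retained as
ground truth, so the generator's labels are an oracle for the text
phenotyping tests. Each output table draws from its own seed substream,
so adding a table leaves the others bit-identical.

Default conditional probabilities were chosen once to resemble the
criterion prevalences seen in treated pediatric HLH cohorts (ferritin
abnormality near-universal among flares, sCD25 ordered in roughly
two-thirds, NK activity rarely tested). What the generator does **not**
emulate: real vital-sign waveforms, free-text variety beyond the
templates, inter-criterion correlation beyond the single latent factor,
transfers and referring-hospital laboratory gaps, or coding behaviour
that varies by payer. Tests passing on synthetic data therefore
demonstrate the *rules* are implemented correctly, not that the rules
are clinically sufficient.

Two further fixtures, `table2_fixture()` and `table3_fixture()`, are
built by direct deterministic placement rather than sampling: a balanced
boolean allocator distributes criterion flags so that every column sum
equals a target count while every row (patient or encounter) stays
within its stratum's criteria-count range. These drive the end-to-end
worked-example checks (mortality rates of 15% vs 13.5%, rate differences
of 1.5 and 1.2 percentage points, a 12.6-day median length-of-stay
difference, a 19% screening yield and a number needed to screen of 5).

## Numerical and testing choices

* Timestamps are timezone-naive UTC at minute resolution — the only
  sub-day arithmetic required is the 60-minute fever span. Canonical
  units are fixed per analyte; unit conversion is out of scope and
  extracts must arrive pre-converted.
* CSV output is deterministic (fixed column order, canonical row sort,
  RFC-4180 quoting), so write–read round-trips are byte-identical and
  pipeline runs can be compared by checksum.
* Property suites compare the criteria engine against a plain-loop
  evaluator on random 20-patient extracts (200 replicates), the negation
  matcher against an exhaustive-window oracle on 1000 random token
  streams, the Fisher path against full hypergeometric enumeration on
  all 2×2 tables with total ≤ 40, the overlap counter against
  per-patient set algebra, and the generator's realized prevalences
  against binomial 99% bounds at 2000 patients. These problem sizes keep
  the default suite in the minutes range while leaving each property
  with substantial coverage.

## Limitations

The package evaluates *rules*, and inherits their blind spots: codes may
mark suspected rather than confirmed disease; criteria over-capture
because sepsis and other hyperinflammatory states satisfy them;
treatment plans under-capture where HLH drugs are ordered outside
oncology workflows; laboratory gaps at referring institutions deflate
criteria counts. The two-group comparison is descriptive — confounding
by indication is untouched, and no survival modelling is attempted.
Genetic/molecular diagnosis pathways and the 2024 revision of the
clinical criteria are out of scope.
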