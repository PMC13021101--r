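# hlhphenotype

Computable phenotypes and treatment outcomes for hemophagocytic
lymphohistiocytosis (HLH) from tabular EHR extracts.

HLH is a life-threatening hyperinflammatory syndrome whose clinical
diagnosis requires **≥ 5 of the 8 HLH-2004 criteria**: fever,
splenomegaly, cytopenia of ≥ 2 lineages (Hgb < 90 g/L, or < 100 g/L in
infants < 4 weeks; platelets < 100×10⁹/L; neutrophils < 1.0×10⁹/L),
triglycerides ≥ 3.0 mmol/L and/or fibrinogen ≤ 1.5 g/L, tissue
hemophagocytosis, low NK-cell activity, ferritin ≥ 500 µg/L, and sCD25
≥ 2400 U/mL. No single EHR field records any of this, so researchers
assembling HLH cohorts must choose between imperfect machine-evaluable
definitions. This package implements, and lets you compare, three:

1. **ICD-10 coding** — any in-window D76.1 or D76.2 code;
2. **Treatment plan** — plan/protocol names containing "HLH" or
   "h(a)emophagocytosis";
3. **Clinical criteria** — ≥ 5 operationalized HLH-2004 criteria within
   one hospital episode, including a two-clause oral fever rule
   (≥ 38.3 °C once, or ≥ 38.0 °C sustained ≥ 60 min) and free-text
   detection of splenomegaly/hemophagocytosis with a 3-token pre-term
   negation window (`no`, `none`, `absence`, `without`, `negative`).

On top of the phenotypes it classifies HLH-directed therapy exposure
(dexamethasone, methylprednisolone, anakinra, ruxolitinib, cyclosporine,
etoposide, emapalumab), derives clinical outcomes (length of stay, ICU,
in-hospital and 30-day mortality, stem-cell transplant), runs the
treated-vs-untreated comparison (Wilcoxon rank-sum; χ²/Fisher;
round-first risk differences with Wald 95% CIs; seeded bootstrap CI for
the median-LOS difference), and summarises a ferritin + fever screening
cohort. A seeded synthetic-EHR generator and deterministic count-placed
fixtures make the whole pipeline testable without patient data.

All user-facing functions take data frames and return tibbles, so calls
chain with the pipe; results support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

The count-placed cohort fixture contains 245 patients who meet ≥ 5
criteria, 193 of whom received HLH-directed therapy at the index
encounter:

```r
library(hlhphenotype)
library(dplyr)

fx          <- table2_fixture()
profiles    <- evaluate_criteria(fx)
assignments <- assign_phenotypes(fx, profiles)
cmp         <- compare_groups(fx, assignments, profiles, seed = 1)

tidy(cmp) |> filter(variable == "outcome")
#>   variable level  n_treated pct_treated n_untreated pct_untreated method p_value
#> 1 outcome  icu          111        57.5          22          42.3 chi-s…  0.0724
#> 2 outcome  in_ho…        29        15             7          13.5 chi-s…  0.950
#> 3 outcome  death…        32        16.6           8          15.4 chi-s…  1.000
#> 4 outcome  sct_a…        13         6.7           1           1.9 Fishe…  0.312

cmp$effects
#>   effect                    estimate estimate_unrounded conf_low conf_high unit
#> 1 in_hospital_mortality_di…     1.5                1.56    -8.99      12.1 perc…
#> 2 mortality_30d_diff            1.20               1.20    -9.93      12.3 perc…
#> 3 median_los_diff              12.6               12.6     12.6       12.6 days
```

In-hospital mortality is 15% among treated and 13.5% among untreated
patients — a 1.5-percentage-point round-first difference (the unrounded
1.56 is reported alongside); treated patients stay a median 12.6 days
longer. The screening cohort answers "how specific is a ferritin + fever
entry rule?":

```r
screening_summary(build_screening_cohort(evaluate_criteria(table3_fixture()))) |>
  glance()
#>   total_encounters n_meeting_threshold share_pct number_needed_to_screen
#> 1             1325                 252        19                       5
```

Only 19% of high-ferritin febrile encounters reach the 5-criteria
threshold: about 5 such patients must be evaluated per qualifying case.

For fully synthetic data:

```r
ex  <- simulate_ehr(n_patients = 300, seed = 42)
out <- run_hlh_pipeline(extract = ex, output_dir = "run1", seed = 42)
compute_overlap(assign_phenotypes(ex))
```

which emits `criteria_profiles.csv`, `phenotypes.csv`, `overlap.json`,
`table1.csv`, `table2.csv`, `table3.csv` and a checksummed
`manifest.json`. A thin CLI over the same functions lives at
`inst/scripts/hlh-pipeline.R` (`generate` and `all` subcommands).

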