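# shieldtext

Rule-based text mining of semistructured rheumatology outpatient letters to
apply the British Society for Rheumatology (BSR) COVID-19 shielding
criteria, with a synthetic letter-corpus generator and diagnostic-accuracy
evaluation built in.

## The problem

At the start of the COVID-19 pandemic, UK rheumatology teams had to identify
clinically extremely vulnerable patients — those who should *shield* — by
manually reading outpatient clinic letters, because outpatient diagnoses and
high-cost drugs (biologics, JAK inhibitors) are recorded only in
semistructured letter text, not as searchable codes. The BSR published a
rule-based risk score over age, comorbidities and immunosuppressive
medication. `shieldtext` automates that review:

1. **Parse** PRSB-style letters into headed sections ("Rheumatological
   diagnoses", "Current medications", "Previous DMARDs", ...).
2. **Code diagnoses** against a small hierarchical terminology
   (SNOMED-style parent/child concepts) and roll them up to the comorbidity
   categories the rules use — so "pneumonia" counts as pre-existing lung
   disease via its parent concept "pneumonitis".
3. **Extract medications** with drug identity (brand → generic → class,
   RxNorm-style), dose, dosing frequency, treatment duration, temporal
   anchors ("last IV cyclophosphamide January 2020") and active/past/planned
   status. The section heading sets the default status; free-text cues
   ("stopped due to nausea", "to start next month") override it.
4. **Consolidate** the two most recent letters before an index date
   (1 April 2020 by default) into one record per patient, most-recent-wins
   when both letters mention the same drug, active medications only.
5. **Score** each patient with a fully configurable rule table:

   *score = min(1, [age ≥ 70] + Σ comorbidity points) + Σ medication points*

   with one point per active scoring drug class, steroid points by daily
   prednisolone-equivalent dose and duration band, cyclophosphamide points
   when the last infusion is within 6 months, and category thresholds
   score ≥ 3 → **shield**, = 2 → **self-isolate**, ≤ 1 → **social
   distance**. Pulmonary hypertension forces shielding regardless of score;
   glucocorticoid taper instructions (whose dose at the index date is
   unknowable from the instruction) route to a **manual review** category.
   A non-numerical risk-stratification *guide* (ordered clauses instead of
   points) ships as an alternative rule set.
6. **Evaluate** predictions against a gold standard: sensitivity,
   specificity, PPV, NPV, likelihood ratios (Wilson and log-method 95% CIs)
   and F1, plus deployment and baseline cohort tables with small-cell
   suppression.

No real patient data are included or required: the `generate_cohort()`
module renders realistic synthetic letters from structured ground truth and
scores that truth with an independent arithmetic oracle, so the whole
pipeline is testable end to end.

## Worked example

A 71-year-old with type 2 diabetes on adalimumab and methotrexate:

```r
library(shieldtext)

txt <- paste("Rheumatological diagnoses:",
             "Other diagnoses:", "Type 2 diabetes",
             "Current medications:",
             "Adalimumab 40mg alternate weeks",
             "Methotrexate 15mg weekly", sep = "\n")
letter <- parse_letter(txt, read_heading_lexicon(), "L1", "P001", "2020-02-01")
rec    <- patient_record("P001", list(letter), birth_date = "1948-10-01")
cr     <- consolidate(rec, "2020-04-01", n_letters = 1)
score_patient(cr)
#> <shielding_result> P001 score 3 -> SHIELD
#>   +1  age 71 >= 70
#>   +1  comorbidity DIABETES
#>   -1  age/comorbidity cap at 1
#>   +1  adalimumab (biologic)
#>   +1  methotrexate (immunosuppressant)
```

The age point and the diabetes point are capped at 1 together; the biologic
and the immunosuppressant score one each; total 3 → shield. Metrics from a
published confusion matrix:

```r
diagnostic_metrics(confusion_counts(tp = 192, fp = 43, fn = 47, tn = 521))
#> Diagnostic accuracy (n = 803 )
#>   Sensitivity: 80% (75%, 85%)
#>   Specificity: 92% (90%, 94%)
#>   PPV:         82% (76%, 86%)
#>   NPV:         92% (89%, 94%)
#>   LR+:         11 (7.85, 14)
#>   LR-:         0.21
#>   FPR: 8%  FNR: 20%
#>   F1 score:    0.81
```

A full synthetic run from the shell:

```sh
Rscript inst/cli/shieldtext.R simulate --n 200 --seed 1 \
    --out corpus.jsonl --truth truth.csv
Rscript inst/cli/shieldtext.R run --corpus corpus.jsonl --outdir out/
```

which writes `parsed.jsonl`, `mentions.csv`, `results.csv` and
`manifest.json` under `out/`.

## Configuration

All rule values (points, steroid bands, cyclophosphamide window, thresholds,
overrides) live in `inst/extdata/bsr_grid.yaml` and
`inst/extdata/bsr_guide.yaml`; the lexicons (headings, diagnoses with
hierarchy, drugs with brands and classes, dosing-frequency multipliers) are
plain TSV under `inst/extdata/`. See `vignettes/shielding-methods.Rmd` for
the modelling choices and their rationale.
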