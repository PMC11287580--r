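---
title: "Automated shielding risk stratification from outpatient letters: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated shielding risk stratification from outpatient letters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shieldtext)
```

# The task and the model

UK rheumatology outpatient letters are semistructured: headed lists of
diagnoses and medications followed by narrative. `shieldtext` turns those
lists into a per-patient structured record at an index date and applies the
British Society for Rheumatology (BSR) COVID-19 shielding score. The score
is deliberately simple — it was written to be applied by busy clinicians —
and the engineering problem is entirely in the text: recognising drugs under
their brand names, reading doses and frequencies, deciding whether a drug
was still active in April 2020, and rolling free-text diagnoses up a concept
hierarchy to the comorbidity categories the rules name.

The scoring model, with every numeric value in `inst/extdata/bsr_grid.yaml`
rather than in code, is:

* **Demographic block.** One point if aged 70 or over at the index date;
  one point per flagged comorbidity (diabetes, ischaemic heart disease,
  hypertension, pre-existing lung disease, chronic kidney impairment,
  rheumatoid arthritis); the whole block is capped at 1 point
  (`demographic_block_cap`).
* **Medications.** One point per active scoring drug class (biologics,
  conventional immunosuppressants, JAK inhibitors). Glucocorticoids score
  by dose/duration band instead of a flat point: ≥ 20 mg/day for ≥ 4 weeks
  → 3; ≥ 5 mg/day for ≥ 4 weeks → 2; any glucocorticoid use → 1.
  Cyclophosphamide scores 3 when the last administration is within 183 days
  of the index date.
* **Categories.** Total ≥ 3 → shield; exactly 2 → self-isolate; otherwise
  social distancing. Pulmonary hypertension forces the shield category
  regardless of score. Rheumatoid arthritis with interstitial lung disease,
  or CTD-associated ILD, sets a *clinical discretion* flag without changing
  the category.

The point values were transcribed into the config from the published
guidance's stated constraints (a biologic plus methotrexate scores 2, two
biologics score 2, RA contributes 1, age/comorbidity capped at 1, highest
weights on high-dose steroids and recent cyclophosphamide, shield at 3+).
Where the guidance leaves a cell open the config comments record the choice;
because every value is configuration, a department could re-run the pipeline
under amended guidance without touching code.

# Text-processing decisions

**Headings.** A line is a heading iff its normalized form (lower-cased,
punctuation stripped, whitespace collapsed, optional trailing colon) is in a
closed heading lexicon (`inst/extdata/headings.tsv`). A closed lexicon is
deterministic and auditable; the shipped lexicon covers the standard PRSB
headings and common synonyms, and is trivially extendable. Lines before any
recognised heading fall into an `OTHER` section and never feed extraction.

**Diagnosis coding.** Matching is exact-after-normalization on a packaged
mini-terminology (~40 concepts with parent links), with a longest-match
token-subsequence fallback ("longstanding rheumatoid arthritis of the
hands" still tags RA). There is no fuzzy matching by default: a stand-in
for a proprietary concept tagger must above all be deterministic and
reviewable. Category rollup walks the parent hierarchy, so "pneumonia"
flags pre-existing lung disease through its parent "pneumonitis" — a
deliberate reproduction of how hierarchy-based coding behaves, including its
known failure mode of counting a possibly acute episode as a chronic
comorbidity. All diagnoses are treated as current; unmatched items are kept
in `unmatched_diagnoses` rather than dropped silently.

**Medication status.** The section heading sets the default
(current/previous/planned); cue phrases in the line override it ("stopped",
"discontinued", "never started" → past; "to start", "to commence" →
planned). Cue override dominance matters because clinicians routinely leave
a stopped drug under the current-medications heading with a stop note.
Only active medications ever score. Unknown-status mentions (from
unrecognised headings) never score.

**Doses and tapers.** Daily-equivalent dose is computed from the stated
quantity and a frequency-multiplier table (od/bd/tds/qds/daily/…, TSV);
weekly-dosed drugs such as methotrexate keep `per_day_mg` absent, since only
glucocorticoid scoring reads the daily dose. A taper instruction
("30 mg to be reduced in 5 mg increments …") leaves the dose at the index
date undefined; rather than guess, the mention is flagged `TAPER` and the
patient routes to a `MANUAL_REVIEW` category under the default policy.
This is the single most consequential design choice: naive handling of
tapers is the dominant cause of under-scoring steroid patients, so the
default routes them to a human, while `review_policy = "score-anyway"` and
`taper_policy = "initial-dose"` reproduce the naive behaviours for
comparison studies.

**Temporal expressions.** Month-only dates resolve to the 15th, year-only
dates to 1 July, numeric dates day-first (UK) by default and configurable.
A cyclophosphamide mention with no recoverable date but active status is
assumed within the window and flagged `LOW_CONFIDENCE`, as is a steroid
whose duration criterion could not be evaluated because the letter states
no duration.

**Consolidation.** The two most recent letters strictly before the index
date are combined (ties on date broken by letter id): diagnoses union
across letters; for a drug present in both, the newer letter's mention
replaces the older entirely. Union-with-recency keeps a drug documented
only in the older letter — dropping it would discard real information the
most recent letter simply did not repeat. Patients with a single eligible
letter consolidate with a warning; no eligible letter is an error.

# Evaluation

Predictions are binarized (shield vs not) and compared with a gold standard
as a 2×2 confusion matrix. Proportion CIs use Wilson score intervals and
likelihood-ratio CIs the standard log method; the method names are recorded
in the metrics metadata because the choice is a convention, not a given.
Totals and derived metrics are always computed from the matrix cells, never
taken from printed marginals. Report rounding is whole percents for
proportions, two decimals for ratios, and nearest integer for a positive
likelihood ratio of 10 or more; because the raw positive likelihood ratio
often sits near a rounding boundary, both roundings are kept in the
metadata. Manual-review rows can be excluded (and counted) or must be
resolved upstream. Cohort tables suppress any non-zero cell below 5
(statistical disclosure control), and deployment tables report per-category
counts and shares for the grid and guide side by side.

# The synthetic corpus and what it does (and does not) show

`generate_cohort()` draws structured truth per patient and renders letters
from it. The defaults emulate a general UK rheumatology outpatient cohort:
age normal(58, 14) truncated to 18–95 years, 60% female, comorbidity
prevalences of 11% diabetes, 5% ischaemic heart disease, 22% hypertension,
26% pre-existing lung disease, 5% chronic kidney impairment, 47% rheumatoid
arthritis, 22% psoriatic arthritis, 17% ankylosing spondylitis, and
medication exposure of 14% glucocorticoids, 50% conventional
immunosuppressants, 52% biologics. Conditions a disclosure-controlled
report would suppress are set to small clinically plausible rates (pulmonary
hypertension 0.4%, JAK inhibitors 2%, cyclophosphamide 1%). Steroid daily
doses are drawn from a grid weighted toward 5–10 mg; stated durations cover
1–24 months with 30% of letters omitting duration. Noise switches add taper
phrasing, stop-notes under the current-medications heading, planned-start
notes and character-level typos, each off by default.

Each patient's truth is also scored by `oracle_score()` — a separate,
minimal arithmetic over the structured truth that shares no code with the
text pipeline — so pipeline-vs-oracle agreement is a genuine
two-implementation check. With all noise off, the pipeline must agree with
the oracle for every patient; the test suite asserts this on a 1,000-patient
cohort, and asserts that with taper noise exactly the taper-bearing patients
route to manual review. Problem sizes in the suite (up to 2,000 patients for
prevalence recovery, 1,000 for end-to-end equivalence) were chosen as the
smallest that make the binomial checks sharp.

What passing these tests shows: the extraction, consolidation and scoring
machinery is internally correct on letters whose structure matches the
generator's grammar. What it does not show: performance on real letters,
whose heading inventory, phrasing variety, typo distribution and narrative
spill-over are far richer than the generator's. The generator produces no
free-text narrative at all, no negations inside diagnosis lines, and no
multi-drug lines; real-world figures (e.g. a sensitivity near 80% against
clinician decisions) cannot be reproduced from synthetic data and are not
claimed by this package.

# Known limitations

* The shipped terminology and drug lexicon are small stand-ins with the
  same interfaces as full SNOMED-CT / RxNorm mappings; coverage, not
  mechanism, is what changes when real terminologies are substituted.
* Disease-activity rules from the later non-numerical guide are not
  evaluated: activity lives in the narrative text, which is out of scope.
* Diagnosis lines are taken as current and un-negated; temporality applies
  to medications only.
* Mid-taper dose inference is deliberately not attempted; such patients are
  surfaced for review rather than scored from a guess.
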