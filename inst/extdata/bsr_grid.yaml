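# BSR COVID-19 numerical scoring grid.
# Every cell value lives here, not in code; the engine assumes only the
# structure (demographic cap, medication class points, steroid dose/duration
# bands, cyclophosphamide window, thresholds, overrides).
#
# Point values are anchored to the constraints stated in the published
# guidance text: one point per scoring medication class (adalimumab +
# methotrexate = 2; two biologics = 2), age/comorbidity block capped at 1,
# shield at 3+, self-isolate at exactly 2, with the highest weights on
# higher steroid doses and recent cyclophosphamide.
name: BSR numerical scoring grid
kind: grid

age_threshold_years: 70
age_point: 1

# one point per comorbidity, but the whole age+comorbidity block is capped
demographic_block_cap: 1
comorbidity_points:
  DIABETES: 1
  ISCHAEMIC_HEART_DISEASE: 1
  HYPERTENSION: 1
  LUNG_DISEASE: 1
  CKD: 1
  RA: 1

med_class_points:
  BIOLOGIC: 1
  IMMUNOSUPPRESSANT: 1
  SMALL_MOLECULE_IS: 1

# ordered by descending minimum daily dose; the first matching band scores.
# A band with min_duration_weeks requires the stated treatment duration;
# unknown duration fails that criterion, so such patients fall to the
# duration-free band below and are flagged LOW_CONFIDENCE.
steroid_bands:
  - min_per_day_mg: 20
    min_duration_weeks: 4
    points: 3
  - min_per_day_mg: 5
    min_duration_weeks: 4
    points: 2
  - min_per_day_mg: 0
    min_duration_weeks: null
    points: 1

# "within the last 6 months" as strict day arithmetic
cyclo_rule:
  route: any
  window_days: 183
  points: 3

overrides:
  - category: PULMONARY_HYPERTENSION
    force: SHIELD

# RA or CTD-associated ILD: clinical discretion flag, not a category change
discretion:
  categories: [CTD_ILD]
  ra_with_ild: true

thresholds:
  shield_min: 3
  self_isolate_exact: 2
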