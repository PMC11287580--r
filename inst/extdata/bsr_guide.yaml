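# BSR risk stratification guide (non-numerical variant): ordered clauses,
# first match wins. Only clauses stated in the main guidance text are
# represented; disease-activity clauses live in the free-text narrative,
# which this tool does not read, and are deliberately absent.
name: BSR risk stratification guide
kind: guide

clauses:
  - id: pulmonary_hypertension
    when: {category: PULMONARY_HYPERTENSION}
    category: SHIELD
  - id: recent_cyclophosphamide
    when: {cyclo_recent: true}
    category: SHIELD
  - id: high_dose_steroid
    when: {steroid_min_per_day_mg: 20, steroid_min_weeks: 4}
    category: SHIELD
  - id: moderate_steroid_plus_immunosuppression
    when: {steroid_min_per_day_mg: 5, steroid_min_weeks: 4, min_other_is_meds: 1}
    category: SHIELD
  - id: moderate_steroid_vulnerable
    when: {steroid_min_per_day_mg: 5, steroid_min_weeks: 4, demographic: true}
    category: SHIELD
  - id: dual_immunosuppression_vulnerable
    when: {min_is_meds: 2, demographic: true}
    category: SHIELD
  - id: dual_immunosuppression
    when: {min_is_meds: 2}
    category: SELF_ISOLATE
  - id: single_immunosuppression_vulnerable
    when: {min_is_meds: 1, demographic: true}
    category: SELF_ISOLATE

default: SOCIAL_DISTANCE
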