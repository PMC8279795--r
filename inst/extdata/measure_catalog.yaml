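# Simplified emulations of 14 ambulatory eCQMs. Each entry keeps the
# structural drivers of cross-facility discrepancy -- age/sex gates,
# diagnosis-dependent denominators, qualifying encounters, lookback windows,
# exclusions, inverse logic -- without the licensed value sets or CQL of the
# official specifications. Concepts refer to concept_registry.csv.
#
# Window types:
#   mp          during the measurement period (closed interval)
#   ever        on or before the period end
#   before_end  within the given years/months/days ending at the period end
#   before_mid  on or before the period midpoint (diagnosis cutoffs)
# Numerator predicates apply to the most recent qualifying observation;
# "missing: met" means absence of any in-window observation satisfies the
# raw numerator (used by the inverse poor-control measure).

measures:
  - id: cms122
    label: "Diabetes: hemoglobin A1c poor control"
    inverse: true
    age: {min: 18, max: 75}
    conditions:
      - {concept: diabetes_dx, window: {type: before_end, years: 2}}
    requires_encounter: true
    exclusions:
      - {concepts: [hospice_care], window: {type: mp}}
    numerator:
      - concepts: [hba1c]
        window: {type: mp}
        predicate: {op: gt, threshold: 9.0, missing: met}

  - id: cms131
    label: "Diabetes: annual eye exam"
    inverse: false
    age: {min: 18, max: 75}
    conditions:
      - {concept: diabetes_dx, window: {type: before_end, years: 2}}
    requires_encounter: true
    exclusions:
      - {concepts: [hospice_care], window: {type: mp}}
    numerator:
      - {concepts: [retinal_exam], window: {type: before_end, months: 24}}

  - id: cms123
    label: "Diabetes: annual foot exam"
    inverse: false
    age: {min: 18, max: 75}
    conditions:
      - {concept: diabetes_dx, window: {type: before_end, years: 2}}
    requires_encounter: true
    exclusions:
      - {concepts: [hospice_care], window: {type: mp}}
    numerator:
      - {concepts: [foot_exam], window: {type: mp}}

  - id: cms134
    label: "Diabetes: attention for nephropathy"
    inverse: false
    age: {min: 18, max: 75}
    conditions:
      - {concept: diabetes_dx, window: {type: before_end, years: 2}}
    requires_encounter: true
    exclusions:
      - {concepts: [hospice_care], window: {type: mp}}
    numerator:
      - {concepts: [nephropathy_screening], window: {type: mp}}
      - {concepts: [ace_arb_medication], window: {type: mp}}
      - {concepts: [nephropathy_dx], window: {type: mp}}

  - id: cms165
    label: "Controlling high blood pressure"
    inverse: false
    age: {min: 18, max: 85}
    conditions:
      - {concept: hypertension_dx, window: {type: before_mid}}
    requires_encounter: true
    exclusions:
      - {concepts: [esrd_dx], window: {type: ever}}
      - {concepts: [pregnancy_dx], window: {type: mp}}
    numerator:
      - concepts: [bp_reading]
        window: {type: mp}
        predicate: {op: bp_lt, systolic: 140, diastolic: 90}

  - id: cms125
    label: "Breast cancer screening"
    inverse: false
    sex: female
    age: {min: 51, max: 74}
    requires_encounter: true
    exclusions:
      - {concepts: [bilateral_mastectomy], window: {type: ever}}
    numerator:
      - {concepts: [mammogram], window: {type: before_end, months: 27}}

  - id: cms124
    label: "Cervical cancer screening"
    inverse: false
    sex: female
    age: {min: 23, max: 64}
    requires_encounter: true
    exclusions:
      - {concepts: [hysterectomy], window: {type: ever}}
    numerator:
      - {concepts: [cervical_cytology], window: {type: before_end, years: 3}}
      - {concepts: [hpv_test], window: {type: before_end, years: 5}, min_age: 30}

  - id: cms130
    label: "Colorectal cancer screening"
    inverse: false
    age: {min: 50, max: 75}
    requires_encounter: true
    exclusions:
      - {concepts: [total_colectomy, colorectal_cancer_dx], window: {type: ever}}
    numerator:
      - {concepts: [fobt], window: {type: mp}}
      - {concepts: [sigmoidoscopy], window: {type: before_end, years: 5}}
      - {concepts: [colonoscopy], window: {type: before_end, years: 10}}

  - id: cms127
    label: "Pneumococcal vaccination of older adults"
    inverse: false
    age: {min: 65, max: 120}
    requires_encounter: true
    numerator:
      - {concepts: [pneumococcal_vaccination], window: {type: ever}}

  - id: cms153
    label: "Chlamydia screening for women"
    inverse: false
    sex: female
    age: {min: 16, max: 24}
    conditions:
      - {concept: sexual_activity_marker, window: {type: mp}}
    requires_encounter: true
    numerator:
      - {concepts: [chlamydia_test], window: {type: mp}}

  - id: cms155
    label: "Pediatric weight assessment: BMI percentile"
    inverse: false
    age: {min: 3, max: 17}
    requires_encounter: true
    exclusions:
      - {concepts: [pregnancy_dx], window: {type: mp}}
    numerator:
      - {concepts: [bmi_percentile], window: {type: mp}}

  - id: cms146
    label: "Appropriate testing for children with pharyngitis"
    inverse: false
    episodic: true
    age: {min: 3, max: 18}
    episode:
      dx_concept: pharyngitis_dx
      antibiotic_concepts: [antibiotic_medication]
      antibiotic_within_days: 3
      prior_antibiotic_days: 30
      test_concepts: [strep_test]
      test_within_days: 3

  - id: cms156
    label: "High-risk medication use in older adults"
    inverse: true
    age: {min: 65, max: 120}
    requires_encounter: true
    exclusions:
      - {concepts: [hospice_care], window: {type: mp}}
    numerator:
      - {concepts: [high_risk_medication], window: {type: mp}}

  - id: cms74
    label: "Primary caries prevention"
    inverse: false
    age: {min: 0, max: 20}
    requires_encounter: true
    numerator:
      - {concepts: [fluoride_varnish], window: {type: mp}}
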