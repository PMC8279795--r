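concept,event_type,has_value,example_code_system,example_code,description
encounter,encounter,FALSE,CPT,99213,Ambulatory visit
diabetes_dx,diagnosis,FALSE,ICD-10-CM,E11.9,Diabetes mellitus diagnosis
hypertension_dx,diagnosis,FALSE,ICD-10-CM,I10,Essential hypertension diagnosis
esrd_dx,diagnosis,FALSE,ICD-10-CM,N18.6,End-stage renal disease
pregnancy_dx,diagnosis,FALSE,ICD-10-CM,Z33.1,Pregnancy
nephropathy_dx,diagnosis,FALSE,ICD-10-CM,E11.21,Diabetic nephropathy
colorectal_cancer_dx,diagnosis,FALSE,ICD-10-CM,C18.9,Colorectal cancer
pharyngitis_dx,diagnosis,FALSE,ICD-10-CM,J02.0,Acute pharyngitis
sexual_activity_marker,flag,FALSE,LOINC,86646-3,Sexual-activity indicator
hospice_care,flag,FALSE,SNOMED,385763009,Hospice care
hba1c,laboratory,TRUE,LOINC,4548-4,Hemoglobin A1c (%)
bp_reading,vital_sign,TRUE,LOINC,85354-9,Blood pressure (systolic/diastolic mm Hg)
bmi_percentile,vital_sign,TRUE,LOINC,59576-9,BMI percentile for age
retinal_exam,procedure,FALSE,CPT,92014,Dilated retinal examination
foot_exam,procedure,FALSE,SNOMED,401191002,Diabetic foot examination
nephropathy_screening,screening,FALSE,LOINC,14959-1,Urine microalbumin screening
mammogram,screening,FALSE,CPT,77067,Screening mammography
cervical_cytology,screening,FALSE,CPT,88175,Cervical cytology (Pap)
hpv_test,screening,FALSE,CPT,87624,High-risk HPV test
fobt,screening,FALSE,LOINC,2335-8,Fecal occult blood test
chlamydia_test,screening,FALSE,LOINC,43304-5,Chlamydia screening test
strep_test,screening,FALSE,LOINC,6559-5,Group A streptococcus test
colonoscopy,procedure,FALSE,CPT,45378,Colonoscopy
sigmoidoscopy,procedure,FALSE,CPT,45330,Flexible sigmoidoscopy
hysterectomy,procedure,FALSE,CPT,58150,Hysterectomy (total)
bilateral_mastectomy,procedure,FALSE,CPT,19303,Bilateral mastectomy
total_colectomy,procedure,FALSE,CPT,44150,Total colectomy
fluoride_varnish,procedure,FALSE,CPT,99188,Fluoride varnish application
pneumococcal_vaccination,immunization,FALSE,CVX,33,Pneumococcal vaccination
ace_arb_medication,medication,FALSE,RxNorm-class,ACE-ARB,ACE inhibitor or ARB order
antibiotic_medication,medication,FALSE,RxNorm-class,ABX,Antibiotic order
high_risk_medication,medication,FALSE,RxNorm-class,HRM,High-risk medication order (older adults)
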