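[
  {
    "condition": "THROMBOSIS_THROMBOEMBOLISM",
    "n_cases": 100,
    "criterion_prevalence": {
      "imaging_confirmed": 0.85,
      "symptoms_at_site": 0.75,
      "clinical_diagnosis_documented": 0.98
    },
    "criterion_missingness": {
      "imaging_confirmed": 0.13,
      "symptoms_at_site": 0.25
    },
    "prop_not_a_case": 0.02,
    "not_a_case_overrides": {
      "clinical_diagnosis_documented": "absent",
      "imaging_confirmed": "absent"
    },
    "age_median": 49,
    "age_min": 16,
    "age_max": 88,
    "prop_male": 0.32,
    "prop_addis": 0.46,
    "prop_eopd": 0.93
  },
  {
    "condition": "GENERALIZED_CONVULSION",
    "n_cases": 38,
    "criterion_prevalence": {
      "witnessed_seizure": 1,
      "bilateral_motor": 0.97,
      "loss_of_consciousness": 1,
      "tonic_and_clonic": 0.55,
      "postictal_state": 0.6
    },
    "criterion_missingness": {
      "bilateral_motor": 0.03,
      "tonic_and_clonic": 0.2,
      "postictal_state": 0.3
    },
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 31,
    "age_min": 14,
    "age_max": 82,
    "prop_male": 0.58,
    "prop_addis": 0.9,
    "prop_eopd": 0.92
  },
  {
    "condition": "THROMBOCYTOPENIA",
    "n_cases": 23,
    "criterion_prevalence": {
      "platelet_lt150": 1,
      "repeat_count_confirmed": 0.4,
      "clinical_bleeding": 0.5
    },
    "criterion_missingness": {
      "repeat_count_confirmed": 0.5,
      "clinical_bleeding": 0.2
    },
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 35,
    "age_min": 13,
    "age_max": 62,
    "prop_male": 0.39,
    "prop_addis": 0.57,
    "prop_eopd": 0.91
  },
  {
    "condition": "GBS_FISHER",
    "n_cases": 11,
    "criterion_prevalence": {
      "bilateral_weakness": 1,
      "flaccid_weakness": 1,
      "dtr_decreased_in_weak_limbs": 0.95,
      "onset_nadir_12h_28d": 1,
      "alt_dx_absent": 1,
      "electrophys_consistent": 0.88,
      "csf_wbc_lt50": 1,
      "csf_protein_elevated": 1
    },
    "criterion_missingness": {
      "electrophys_consistent": 0.27,
      "csf_wbc_lt50": 0.91,
      "csf_protein_elevated": 0.91
    },
    "prop_not_a_case": 0.09,
    "not_a_case_overrides": {
      "alt_dx_absent": "absent"
    },
    "age_median": 26,
    "age_min": 15,
    "age_max": 58,
    "prop_male": 0.36,
    "prop_addis": 0.55,
    "prop_eopd": 0.64
  },
  {
    "condition": "MYOCARDITIS",
    "n_cases": 12,
    "criterion_prevalence": {
      "compatible_symptoms": 0.85,
      "biomarker_elevated": 0.85,
      "echo_abnormal": 0.5,
      "cmr_abnormal": 0.1,
      "ecg_abnormal": 0.6,
      "histopathology_myocardial_inflammation": 0.05
    },
    "criterion_missingness": {
      "echo_abnormal": 0.4,
      "cmr_abnormal": 0.85,
      "ecg_abnormal": 0.2,
      "histopathology_myocardial_inflammation": 0.9
    },
    "prop_not_a_case": 0.17,
    "not_a_case_overrides": {
      "compatible_symptoms": "absent",
      "biomarker_elevated": "absent",
      "histopathology_myocardial_inflammation": "absent"
    },
    "age_median": 29,
    "age_min": 17,
    "age_max": 83,
    "prop_male": 0.67,
    "prop_addis": 0.5,
    "prop_eopd": 0.08
  },
  {
    "condition": "PERICARDITIS",
    "n_cases": 12,
    "criterion_prevalence": {
      "typical_chest_pain": 0.9,
      "pericardial_rub": 0.35,
      "ecg_typical": 0.6,
      "effusion_imaging": 0.5,
      "chest_radiograph_suggestive": 0.5,
      "histopathology": 0.02
    },
    "criterion_missingness": {
      "ecg_typical": 0.2,
      "chest_radiograph_suggestive": 0.2,
      "effusion_imaging": 0.3,
      "histopathology": 0.95
    },
    "prop_not_a_case": 0.08,
    "not_a_case_overrides": {
      "typical_chest_pain": "absent",
      "pericardial_rub": "absent",
      "ecg_typical": "absent",
      "effusion_imaging": "absent",
      "chest_radiograph_suggestive": "absent",
      "histopathology": "absent"
    },
    "age_median": 29,
    "age_min": 17,
    "age_max": 83,
    "prop_male": 0.67,
    "prop_addis": 0.5,
    "prop_eopd": 0.08
  },
  {
    "condition": "ENCEPHALITIS",
    "n_cases": 2,
    "criterion_prevalence": {
      "focal_cns_sign": 1,
      "fever": 0.6,
      "csf_pleocytosis": 0.5,
      "eeg_consistent": 0.5,
      "neuroimaging_consistent": 0.5
    },
    "criterion_missingness": {
      "fever": 0.9,
      "csf_pleocytosis": 0.9,
      "eeg_consistent": 0.9,
      "neuroimaging_consistent": 0.9
    },
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 24,
    "age_min": 21,
    "age_max": 26,
    "prop_male": 0,
    "prop_addis": 1,
    "prop_eopd": 0.5
  },
  {
    "condition": "MYELITIS",
    "n_cases": 2,
    "criterion_prevalence": {
      "focal_cns_sign": 1,
      "fever": 0.6,
      "csf_pleocytosis": 0.5,
      "eeg_consistent": 0.5,
      "neuroimaging_consistent": 0.5
    },
    "criterion_missingness": {
      "fever": 0.9,
      "csf_pleocytosis": 0.9,
      "eeg_consistent": 0.9,
      "neuroimaging_consistent": 0.9
    },
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 24,
    "age_min": 21,
    "age_max": 26,
    "prop_male": 0,
    "prop_addis": 1,
    "prop_eopd": 0.5
  },
  {
    "condition": "ADEM",
    "n_cases": 2,
    "criterion_prevalence": {
      "clinical_features": 1,
      "physician_diagnosis": 0.5,
      "supportive_test": 0.3,
      "alt_dx_absent": 0.2
    },
    "criterion_missingness": [],
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 24,
    "age_min": 21,
    "age_max": 26,
    "prop_male": 0,
    "prop_addis": 1,
    "prop_eopd": 0.5
  },
  {
    "condition": "BELLS_PALSY",
    "n_cases": 1,
    "criterion_prevalence": {
      "clinical_features": 1,
      "physician_diagnosis": 0.5,
      "supportive_test": 0.3,
      "alt_dx_absent": 0.2
    },
    "criterion_missingness": [],
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 52,
    "age_min": 52,
    "age_max": 52,
    "prop_male": 1,
    "prop_addis": 0,
    "prop_eopd": 1
  },
  {
    "condition": "INJECTION_SITE_ABSCESS",
    "n_cases": 0,
    "criterion_prevalence": [],
    "criterion_missingness": [],
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 30,
    "age_min": 18,
    "age_max": 60,
    "prop_male": 0.5,
    "prop_addis": 0.5,
    "prop_eopd": 0.5
  },
  {
    "condition": "TTS",
    "n_cases": 0,
    "criterion_prevalence": [],
    "criterion_missingness": [],
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 30,
    "age_min": 18,
    "age_max": 60,
    "prop_male": 0.5,
    "prop_addis": 0.5,
    "prop_eopd": 0.5
  },
  {
    "condition": "ANAPHYLAXIS",
    "n_cases": 0,
    "criterion_prevalence": [],
    "criterion_missingness": [],
    "prop_not_a_case": 0,
    "not_a_case_overrides": [],
    "age_median": 30,
    "age_min": 18,
    "age_max": 60,
    "prop_male": 0.5,
    "prop_addis": 0.5,
    "prop_eopd": 0.5
  }
]
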