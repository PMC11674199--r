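{
  "condition": "THROMBOSIS_THROMBOEMBOLISM",
  "version": "aesiloc-1",
  "criteria": [
    {
      "id": "imaging_confirmed",
      "label": "Site-specific imaging confirmation of thrombosis",
      "category": "IMAGING"
    },
    {
      "id": "symptoms_at_site",
      "label": "Symptoms or signs at the thrombosis site",
      "category": "CLINICAL"
    },
    {
      "id": "clinical_diagnosis_documented",
      "label": "Documented clinical diagnosis of thrombosis/thromboembolism",
      "category": "CLINICAL"
    }
  ],
  "levels": {
    "1": [
      "ALL",
      "imaging_confirmed",
      "symptoms_at_site"
    ],
    "2": "imaging_confirmed",
    "3": [
      "ANY",
      "imaging_confirmed",
      "clinical_diagnosis_documented"
    ]
  }
}
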