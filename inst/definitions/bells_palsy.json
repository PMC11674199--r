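{
  "condition": "BELLS_PALSY",
  "version": "aesiloc-1-schema-example",
  "criteria": [
    {
      "id": "clinical_features",
      "label": "Compatible clinical features",
      "category": "CLINICAL"
    },
    {
      "id": "physician_diagnosis",
      "label": "Physician diagnosis documented",
      "category": "CLINICAL"
    },
    {
      "id": "supportive_test",
      "label": "Supportive diagnostic test",
      "category": "LABORATORY"
    },
    {
      "id": "alt_dx_absent",
      "label": "Absence of identified alternative diagnosis",
      "category": "EXCLUSION"
    }
  ],
  "levels": {
    "1": [
      "ALL",
      "clinical_features",
      "physician_diagnosis",
      "supportive_test",
      "alt_dx_absent"
    ],
    "2": [
      "ALL",
      "clinical_features",
      "physician_diagnosis",
      "alt_dx_absent"
    ],
    "3": [
      "ALL",
      "clinical_features",
      "alt_dx_absent"
    ]
  }
}
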