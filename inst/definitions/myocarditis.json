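{
  "condition": "MYOCARDITIS",
  "version": "aesiloc-1",
  "criteria": [
    {
      "id": "histopathology_myocardial_inflammation",
      "label": "Histopathologic demonstration of myocardial inflammation",
      "category": "LABORATORY"
    },
    {
      "id": "biomarker_elevated",
      "label": "Elevated myocardial biomarkers",
      "category": "LABORATORY"
    },
    {
      "id": "cmr_abnormal",
      "label": "Cardiac MR imaging abnormality",
      "category": "IMAGING"
    },
    {
      "id": "echo_abnormal",
      "label": "Echocardiographic abnormality",
      "category": "IMAGING"
    },
    {
      "id": "compatible_symptoms",
      "label": "Compatible cardiac symptoms",
      "category": "CLINICAL"
    },
    {
      "id": "ecg_abnormal",
      "label": "ECG abnormality",
      "category": "ELECTROPHYSIOLOGY"
    }
  ],
  "levels": {
    "1": [
      "ANY",
      "histopathology_myocardial_inflammation",
      [
        "ALL",
        "biomarker_elevated",
        [
          "ANY",
          "cmr_abnormal",
          "echo_abnormal"
        ]
      ]
    ],
    "2": [
      "ANY",
      [
        "ANY",
        "histopathology_myocardial_inflammation",
        [
          "ALL",
          "biomarker_elevated",
          [
            "ANY",
            "cmr_abnormal",
            "echo_abnormal"
          ]
        ]
      ],
      [
        "ALL",
        "biomarker_elevated",
        "compatible_symptoms"
      ]
    ],
    "3": [
      "ANY",
      [
        "ANY",
        "histopathology_myocardial_inflammation",
        [
          "ALL",
          "biomarker_elevated",
          [
            "ANY",
            "cmr_abnormal",
            "echo_abnormal"
          ]
        ]
      ],
      [
        "ALL",
        "biomarker_elevated",
        "compatible_symptoms"
      ],
      [
        "ALL",
        "compatible_symptoms",
        [
          "ANY",
          "ecg_abnormal",
          "biomarker_elevated"
        ]
      ]
    ]
  }
}
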