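{
  "condition": "PERICARDITIS",
  "version": "aesiloc-1",
  "criteria": [
    {
      "id": "typical_chest_pain",
      "label": "Typical pericarditic chest pain",
      "category": "CLINICAL"
    },
    {
      "id": "pericardial_rub",
      "label": "Pericardial friction rub",
      "category": "CLINICAL"
    },
    {
      "id": "ecg_typical",
      "label": "Typical ECG changes",
      "category": "ELECTROPHYSIOLOGY"
    },
    {
      "id": "effusion_imaging",
      "label": "Pericardial effusion on imaging",
      "category": "IMAGING"
    },
    {
      "id": "chest_radiograph_suggestive",
      "label": "Suggestive chest radiograph",
      "category": "IMAGING"
    },
    {
      "id": "histopathology",
      "label": "Histopathologic evidence of pericarditis",
      "category": "LABORATORY"
    }
  ],
  "levels": {
    "1": [
      "ANY",
      "histopathology",
      [
        "AT_LEAST",
        2,
        "typical_chest_pain",
        "pericardial_rub",
        "ecg_typical",
        "effusion_imaging"
      ]
    ],
    "2": [
      "ANY",
      [
        "ANY",
        "histopathology",
        [
          "AT_LEAST",
          2,
          "typical_chest_pain",
          "pericardial_rub",
          "ecg_typical",
          "effusion_imaging"
        ]
      ],
      [
        "ALL",
        [
          "AT_LEAST",
          1,
          "typical_chest_pain",
          "pericardial_rub"
        ],
        [
          "AT_LEAST",
          1,
          "ecg_typical",
          "effusion_imaging",
          "chest_radiograph_suggestive"
        ]
      ]
    ],
    "3": [
      "ANY",
      [
        "ANY",
        "histopathology",
        [
          "AT_LEAST",
          2,
          "typical_chest_pain",
          "pericardial_rub",
          "ecg_typical",
          "effusion_imaging"
        ]
      ],
      [
        "ALL",
        [
          "AT_LEAST",
          1,
          "typical_chest_pain",
          "pericardial_rub"
        ],
        [
          "AT_LEAST",
          1,
          "ecg_typical",
          "effusion_imaging",
          "chest_radiograph_suggestive"
        ]
      ],
      [
        "ALL",
        "typical_chest_pain",
        [
          "ANY",
          "ecg_typical",
          "chest_radiograph_suggestive",
          "effusion_imaging",
          "pericardial_rub"
        ]
      ]
    ]
  }
}
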