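{
  "condition": "ENCEPHALITIS",
  "version": "aesiloc-1",
  "criteria": [
    {
      "id": "focal_cns_sign",
      "label": "Encephalopathy or focal CNS sign",
      "category": "CLINICAL"
    },
    {
      "id": "fever",
      "label": "Fever (CNS inflammation indicator)",
      "category": "CLINICAL"
    },
    {
      "id": "csf_pleocytosis",
      "label": "CSF pleocytosis",
      "category": "LABORATORY"
    },
    {
      "id": "eeg_consistent",
      "label": "EEG consistent with encephalopathy",
      "category": "ELECTROPHYSIOLOGY"
    },
    {
      "id": "neuroimaging_consistent",
      "label": "Neuroimaging consistent with CNS inflammation",
      "category": "IMAGING"
    },
    {
      "id": "histopathology",
      "label": "Histopathologic evidence of CNS inflammation",
      "category": "LABORATORY"
    }
  ],
  "levels": {
    "1": [
      "ALL",
      "focal_cns_sign",
      [
        "ANY",
        "histopathology",
        [
          "ALL",
          "neuroimaging_consistent",
          "csf_pleocytosis"
        ]
      ]
    ],
    "2": [
      "ANY",
      [
        "ALL",
        "focal_cns_sign",
        [
          "ANY",
          "histopathology",
          [
            "ALL",
            "neuroimaging_consistent",
            "csf_pleocytosis"
          ]
        ]
      ],
      [
        "ALL",
        "focal_cns_sign",
        [
          "AT_LEAST",
          2,
          "fever",
          "csf_pleocytosis",
          "eeg_consistent",
          "neuroimaging_consistent"
        ]
      ]
    ],
    "3": [
      "ANY",
      [
        "ALL",
        "focal_cns_sign",
        [
          "ANY",
          "histopathology",
          [
            "ALL",
            "neuroimaging_consistent",
            "csf_pleocytosis"
          ]
        ]
      ],
      [
        "ALL",
        "focal_cns_sign",
        [
          "AT_LEAST",
          2,
          "fever",
          "csf_pleocytosis",
          "eeg_consistent",
          "neuroimaging_consistent"
        ]
      ],
      [
        "ALL",
        "focal_cns_sign",
        [
          "AT_LEAST",
          1,
          "fever",
          "csf_pleocytosis",
          "eeg_consistent",
          "neuroimaging_consistent"
        ]
      ]
    ]
  }
}
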