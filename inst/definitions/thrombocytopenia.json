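{
  "condition": "THROMBOCYTOPENIA",
  "version": "aesiloc-1",
  "criteria": [
    {
      "id": "platelet_lt150",
      "label": "Platelet count < 150 x 10^9/L",
      "category": "LABORATORY"
    },
    {
      "id": "repeat_count_confirmed",
      "label": "Confirmed on repeat platelet count",
      "category": "LABORATORY"
    },
    {
      "id": "clinical_bleeding",
      "label": "Clinical bleeding manifestations",
      "category": "CLINICAL"
    }
  ],
  "levels": {
    "1": [
      "ALL",
      "platelet_lt150",
      "repeat_count_confirmed"
    ],
    "2": "platelet_lt150",
    "3": [
      "ANY",
      "platelet_lt150",
      "clinical_bleeding"
    ]
  }
}
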