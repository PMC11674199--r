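{
  "condition": "GENERALIZED_CONVULSION",
  "version": "aesiloc-1",
  "criteria": [
    {
      "id": "witnessed_seizure",
      "label": "Witnessed sudden loss of consciousness with motor seizure",
      "category": "CLINICAL"
    },
    {
      "id": "bilateral_motor",
      "label": "Motor involvement of both right and left limbs",
      "category": "CLINICAL"
    },
    {
      "id": "loss_of_consciousness",
      "label": "Loss of consciousness",
      "category": "CLINICAL"
    },
    {
      "id": "tonic_and_clonic",
      "label": "Tonic and clonic motor manifestations",
      "category": "CLINICAL"
    },
    {
      "id": "postictal_state",
      "label": "Post-ictal state documented",
      "category": "CLINICAL"
    }
  ],
  "levels": {
    "1": [
      "ALL",
      "witnessed_seizure",
      "bilateral_motor",
      "loss_of_consciousness",
      "tonic_and_clonic"
    ],
    "2": [
      "ALL",
      "witnessed_seizure",
      "bilateral_motor",
      "loss_of_consciousness",
      [
        "ANY",
        "tonic_and_clonic",
        "postictal_state"
      ]
    ],
    "3": [
      "ALL",
      "witnessed_seizure",
      "bilateral_motor",
      "loss_of_consciousness"
    ]
  }
}
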