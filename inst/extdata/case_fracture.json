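{
  "comment": "Published fracture case study transcription; weight/height were not specified.",
  "sex": "unspecified",
  "weight_kg": null,
  "height_cm": null,
  "responses": {
    "G1.Q1": "no", "G1.Q2": "no", "G1.Q3": "no", "G1.Q4": "no", "G1.Q5": "no", "G1.Q6": "no",
    "G2.Q1": "yes", "G2.Q2": "yes", "G2.Q3": "no",
    "G3-A.Q1": "yes", "G3-A.Q2": "yes", "G3-A.Q3": "yes",
    "G3-B.Q4": "yes", "G3-B.Q5": "no", "G3-B.Q6": "yes", "G3-B.Q7": "no", "G3-B.Q9": "yes"
  }
}
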