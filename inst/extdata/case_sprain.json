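{
  "comment": "Published sprain case study transcription; weight/height were not specified.",
  "sex": "unspecified",
  "weight_kg": null,
  "height_cm": null,
  "responses": {
    "G1.Q1": "no", "G1.Q2": "no", "G1.Q3": "no", "G1.Q4": "no", "G1.Q5": "no", "G1.Q6": "yes",
    "G2.Q1": "no", "G2.Q2": "no", "G2.Q3": "yes",
    "G3-A.Q1": "yes", "G3-A.Q2": "no", "G3-A.Q3": "no",
    "G3-B.Q4": "no", "G3-B.Q5": "no", "G3-B.Q6": "no", "G3-B.Q7": "no", "G3-B.Q9": "no",
    "G4-A.Q1": "yes", "G4-A.Q2": "yes", "G4-A.Q3": "yes",
    "G4-B.Q1": "yes", "G4-B.Q2": "yes", "G4-B.Q3": "yes"
  }
}
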