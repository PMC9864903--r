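{
  "sex": "female",
  "body_mass_kg": 56.8,
  "remainder_organs": ["adrenals", "brain", "small intestine", "kidneys", "muscle", "pancreas", "spleen", "thymus"],
  "provenance": "adult female reference phantom organ masses, OLINDA 1.1 style conventions; editable"
}
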