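{
  "sex": "male",
  "body_mass_kg": 73.7,
  "remainder_organs": ["adrenals", "brain", "small intestine", "kidneys", "muscle", "pancreas", "spleen", "thymus"],
  "provenance": "adult hermaphrodite/male reference phantom organ masses, OLINDA 1.1 style conventions; editable"
}
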