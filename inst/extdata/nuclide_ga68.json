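{
  "name": "Ga-68",
  "half_life_min": 67.71,
  "np_energy_mev": 0.740,
  "branching": 0.891,
  "provenance": "standard nuclear data (NNDC); np energy is the mean non-penetrating emission per decay"
}
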