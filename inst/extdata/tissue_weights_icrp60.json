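{
  "weights": {
    "gonads": 0.20,
    "red marrow": 0.12,
    "colon": 0.12,
    "lungs": 0.12,
    "stomach wall": 0.12,
    "urinary bladder wall": 0.05,
    "breasts": 0.05,
    "liver": 0.05,
    "esophagus": 0.05,
    "thyroid": 0.05,
    "skin": 0.01,
    "osteogenic cells": 0.01
  },
  "remainder_weight": 0.05,
  "colon_split": [0.57, 0.43],
  "esophagus_surrogate": "thymus",
  "provenance": "ICRP Publication 60 tissue weighting factors; colon split and esophagus surrogate per OLINDA 1.1 usage"
}
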