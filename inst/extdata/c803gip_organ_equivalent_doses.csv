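organ,male_mSv_per_MBq,female_mSv_per_MBq
adrenals,0.00936,0.0124
brain,0.000541,0.000658
breasts,0.000934,0.00113
gallbladder wall,0.00515,0.00555
lli wall,0.00166,0.00196
small intestine,0.0031,0.00398
stomach wall,0.00335,0.00374
uli wall,0.00309,0.00371
heart wall,0.0319,0.0362
kidneys,0.713,0.773
liver,0.006,0.00754
lungs,0.00576,0.0073
muscle,0.00227,0.00306
pancreas,0.00777,0.0089
red marrow,0.014,0.0135
osteogenic cells,0.0109,0.0145
skin,0.000859,0.001
spleen,0.0101,0.0124
gonads,0.00137,0.00189
thymus,0.00178,0.00198
thyroid,0.000487,0.000543
urinary bladder wall,0.00152,0.00202
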