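organ,mass_g
adrenals,14.0
brain,1200
breasts,360
gallbladder wall,8.0
lli wall,143
small intestine,600
stomach wall,140
uli wall,200
heart wall,240
kidneys,275
liver,1400
lungs,800
muscle,17000
pancreas,85
red marrow,1050
osteogenic cells,100
skin,2300
spleen,150
ovaries,8.7
thymus,20.0
thyroid,17.0
urinary bladder wall,35.9
blood,4100
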