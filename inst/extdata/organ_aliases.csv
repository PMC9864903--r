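alias,canonical
kidney,kidneys
heart,heart wall
stomach,stomach wall
lung,lungs
breast,breasts
adrenal,adrenals
gallbladder,gallbladder wall
large intestine,uli wall
large intestine wall,uli wall
urinary bladder,urinary bladder wall
urinary bladder (rinsed),urinary bladder wall
bone,osteogenic cells
osteogenic cells,osteogenic cells
bone marrow,red marrow
marrow,red marrow
testis,testes
ovary,ovaries
intestine,small intestine
small intestine (without content),small intestine
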