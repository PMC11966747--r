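name,op_class,active_species,ic50_uM,correction_divisor
chlorpyrifos,diethyl_organothiophosphate,chlorpyrifos oxon,0.38,1
diazinon,diethyl_organothiophosphate,diazoxon,1.82,1
fenitrothion,dimethyl_organothiophosphate,fenitrooxon,0.84,10
methyl parathion,dimethyl_organothiophosphate,methyl paraoxon,0.14,10
profenofos,oxon,profenofos,94.5,1
chlorfenvinphos,oxon,chlorfenvinphos,27.7,1
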