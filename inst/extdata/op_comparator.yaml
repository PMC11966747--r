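# Comparator exposure: chlorpyrifos at its 2 mg/kg BW NOAEL, where the
# predicted blood oxon concentration equals the in vitro BMCL05 of
# chlorpyrifos oxon. EAR_comparator = bmcl05_uM / ic50_uM, kept unrounded.
compound: chlorpyrifos
bmcl05_uM: 0.015
ic50_uM: 0.38
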