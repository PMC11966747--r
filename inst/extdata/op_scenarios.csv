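compound,dose_mg_per_kg,ingested_amount_mg,body_weight_kg,cbmax_oxon_uM,cbmax_is_corrected,reported_ear_test,reported_dcr,reported_outcome,source_note
chlorpyrifos,0.01,,70,0.000068,TRUE,0.00018,0.0046,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,0.012,,70,0.000082,TRUE,0.00022,0.0050,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,0.014,,70,0.000096,TRUE,0.00025,0.0064,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,0.03,,70,0.00021,TRUE,0.00054,0.014,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,0.1,,70,0.00069,TRUE,0.0018,0.046,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,0.5,,70,0.0035,TRUE,0.0092,0.23,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,1,,70,0.0072,TRUE,0.019,0.48,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,2,,70,0.015,TRUE,0.040,1.0,negative,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,214,,70,0.57,TRUE,1.50,38,positive,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,286,,70,0.60,TRUE,1.57,40,positive,single oral exposure; dose already normalised to 70 kg BW
chlorpyrifos,300,,70,0.60,TRUE,1.58,40,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,0.011,,70,0.000015,TRUE,0.0000083,0.00021,negative,single oral exposure; dose already normalised to 70 kg BW
diazinon,0.03,,70,0.000041,TRUE,0.000023,0.00057,negative,single oral exposure; dose already normalised to 70 kg BW
diazinon,0.12,,70,0.00016,TRUE,0.000091,0.0023,negative,single oral exposure; dose already normalised to 70 kg BW
diazinon,0.20,,70,0.00028,TRUE,0.00015,0.0038,negative,single oral exposure; dose already normalised to 70 kg BW
diazinon,0.21,,70,0.00029,TRUE,0.00016,0.0040,unknown,single oral exposure; dose already normalised to 70 kg BW
diazinon,0.30,,70,0.00041,TRUE,0.00023,0.0058,unknown,single oral exposure; dose already normalised to 70 kg BW
diazinon,200,,70,0.15,TRUE,0.084,2.1,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,214,,70,0.15,TRUE,0.085,2.2,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,293,,70,0.16,TRUE,0.089,2.3,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,323,,70,0.16,TRUE,0.090,2.3,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,357,,70,0.17,TRUE,0.091,2.3,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,429,,70,0.17,TRUE,0.093,2.3,positive,single oral exposure; dose already normalised to 70 kg BW
diazinon,643,,70,0.17,TRUE,0.095,2.4,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.042,,70,0.0057,TRUE,0.0068,0.17,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.06,,70,0.0082,TRUE,0.0097,0.25,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.083,,70,0.011,TRUE,0.013,0.34,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.09,,70,0.012,TRUE,0.015,0.37,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.17,,70,0.023,TRUE,0.028,0.70,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.18,,70,0.025,TRUE,0.029,0.74,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.25,,70,0.034,TRUE,0.041,1.0,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.33,,70,0.045,TRUE,0.054,1.4,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,0.36,,70,0.049,TRUE,0.059,1.5,negative,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,36,,70,5.79,TRUE,6.89,174,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,71,,70,11.47,TRUE,13.66,346,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,143,,70,20.24,TRUE,24.10,610,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,214,,70,26.90,TRUE,32.03,811,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,286,,70,33.34,TRUE,39.69,1005,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,357,,70,39.42,TRUE,46.93,1189,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,429,,70,45.24,TRUE,53.86,1364,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,500,,70,50.60,TRUE,60.24,1526,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,536,,70,53.18,TRUE,63.31,1604,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,571,,70,55.60,TRUE,66.18,1677,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,714,,70,64.64,TRUE,76.95,1949,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,1714,,70,100.71,TRUE,119.90,3037,positive,single oral exposure; dose already normalised to 70 kg BW
fenitrothion,1786,,70,102.06,TRUE,121.49,3078,positive,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,0.003,,70,0.00051,TRUE,0.0036,0.092,negative,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,0.029,,70,0.0049,TRUE,0.035,0.89,negative,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,0.057,,70,0.0097,TRUE,0.069,1.8,negative,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,0.30,,70,0.051,TRUE,0.36,9.2,negative,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,26,,70,5.12,TRUE,36.59,927,positive,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,171,,70,28.50,TRUE,203.58,5157,positive,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,286,,70,40.69,TRUE,290.61,7362,positive,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,714,,70,71.03,TRUE,507.39,12854,positive,single oral exposure; dose already normalised to 70 kg BW
methyl parathion,1143,,70,84.26,TRUE,601.86,15247,positive,single oral exposure; dose already normalised to 70 kg BW
profenofos,1600,,70,1015.56,TRUE,10.75,272,positive,single oral exposure; dose already normalised to 70 kg BW
chlorfenvinphos,0.04,,70,0.0041,TRUE,0.00015,0.0038,negative,single oral exposure; dose already normalised to 70 kg BW
chlorfenvinphos,0.18,,70,0.019,TRUE,0.00068,0.017,unknown,single oral exposure; dose already normalised to 70 kg BW
chlorfenvinphos,1,,70,0.11,TRUE,0.0039,0.098,negative,single oral exposure; dose already normalised to 70 kg BW
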