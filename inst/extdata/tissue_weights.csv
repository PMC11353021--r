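set,organ,weight
ICRP103,gonads,0.08
ICRP103,bone_marrow,0.12
ICRP103,colon,0.12
ICRP103,lung,0.12
ICRP103,stomach,0.12
ICRP103,breast,0.12
ICRP103,bladder,0.04
ICRP103,esophagus,0.04
ICRP103,liver,0.04
ICRP103,thyroid,0.04
ICRP103,skin,0.01
ICRP103,brain,0.01
ICRP103,salivary_glands,0.01
ICRP103,kidneys,0.0092
ICRP103,uterus,0.0092
ICRP103,prostate,0.0092
ICRP103,eye_lens,0
ICRP60,gonads,0.2
ICRP60,bone_marrow,0.12
ICRP60,colon,0.12
ICRP60,lung,0.12
ICRP60,stomach,0.12
ICRP60,bladder,0.05
ICRP60,breast,0.05
ICRP60,liver,0.05
ICRP60,esophagus,0.05
ICRP60,thyroid,0.05
ICRP60,skin,0.01
ICRP60,brain,0.005
ICRP60,salivary_glands,0.005
ICRP60,kidneys,0.005
ICRP60,uterus,0.005
ICRP60,prostate,0.005
ICRP60,eye_lens,0
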