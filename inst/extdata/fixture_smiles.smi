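CC(=O)Oc1ccccc1C(=O)O aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O quercetin
Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1 resveratrol
COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O curcumin
CC(N)C(=O)O alanine
OCC1OC(O)C(O)C(O)C1O glucose
CC(C)C1CCC(C)CC1O menthol
CC(=CCCC(C)C1CC=C(C)C1)C limonene
Oc1ccc(C2CC(=O)c3c(O)cc(O)cc3O2)cc1 naringenin
CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5 morphine
CC(C)Cc1ccc(C(C)C(=O)O)cc1 ibuprofen
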