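compound,substituent,pka,pka_se
L-DOPA,NA,8.81,0.19
DA,NA,8.99,0.05
DHHCA,H,8.87,0.12
6-BromoDHHCA,Br,8.36,0.07
6-CyanoDHHCA,CN,7.51,0.06
6-NitroDHHCA,NO2,6.94,0.06
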