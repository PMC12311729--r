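compound,homologue,km_uM,km_se,kcat_s,kcat_se,ksp_x100,ksp_x100_se,km_o2_uM,km_o2_se,ksp_o2_x100,ksp_o2_x100_se
DHHCA,S. lincolnensis,922,152,2.1,0.2,13.4,2.5,192,33,19.2,3.2
DHHCA,S. hygroscopicus jingganensis,422,94,0.67,0.05,9.5,2.3,1059,246,17.7,2.6
6-BromoDHHCA,S. lincolnensis,205,24,0.16,0.0046,4.6,0.5,280,45,3.5,0.5
6-BromoDHHCA,S. hygroscopicus jingganensis,926,169,1.5,0.1,9.8,1.9,759,66,15.8,1.0
6-CyanoDHHCA,S. lincolnensis,131,16,0.00067,0.000028,0.031,0.0039,563,150,0.014,0.003
6-CyanoDHHCA,S. hygroscopicus jingganensis,228,53,0.0011,0.0001,0.028,0.0071,1019,236,0.040,0.006
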