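compound,ph,ep_a_mV,ep_c_mV,e_half_mV,delta_ep_mV,peak_ratio
L-DOPA,7.4,315,NA,NA,NA,NA
DA,7.4,178,54,116,124,1.32
DHHCA,7.4,333,-95,119,428,1.30
6-BromoDHHCA,7.4,195,59,127,136,1.21
6-CyanoDHHCA,7.4,272,147,209.5,125,1.96
6-NitroDHHCA,7.4,288,NA,NA,NA,NA
L-DOPA,6.0,362,101,231.5,261,5.90
DA,6.0,354,84,219,270,2.89
DHHCA,6.0,388,9,198.5,379,2.54
6-BromoDHHCA,6.0,267,154,210.5,113,1.43
6-CyanoDHHCA,6.0,358,260,309,98,3.92
6-NitroDHHCA,6.0,444,NA,NA,NA,NA
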