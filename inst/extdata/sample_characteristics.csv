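measure,m_asd,sd_asd,n_asd,m_td,sd_td,n_td
Age,40.84,12.12,24,37.05,12.66,24
AQ,41.50,3.81,24,14.61,5.87,23
EQ,11.96,5.38,24,47.96,10.79,23
SPQ,59.92,17.48,24,60.04,17.22,23
WST,111.46,11.74,24,110.67,8.35,24
D2,103.83,9.50,24,100.04,7.79,24
IQ,114.38,16.48,24,108.50,13.07,24
PIQ,110.67,17.65,24,102.38,13.66,24
VIQ,115.00,15.95,24,112.17,12.61,24
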