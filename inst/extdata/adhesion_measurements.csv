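R1_nm,R2_nm,two_theta_deg
38.5,40,119
30.3,43.89,125.1
29.1,33.04,97.7
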