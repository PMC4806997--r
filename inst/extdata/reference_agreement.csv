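measure,cor,cov_percent
fgt_cm3,29.4,7.6
total_cm3,64.1,4.7
pct_fgt,4.3,4.3
c,0.38,12.0
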