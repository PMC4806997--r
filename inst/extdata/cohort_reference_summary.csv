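dataset,fgt_cm3_mean,fgt_cm3_sd,total_cm3_mean,total_cm3_sd,pct_fgt_mean,pct_fgt_sd,c_mean,c_sd
hr_gre_pd,143.7,63.5,492.6,299.2,36.3,16.5,1.21,0.16
hr_gre_pd_r,135.2,56.2,482.6,296.2,35.4,16.2,1.07,0.18
hr_gre_t1,157.6,69.5,492.6,299.2,39.2,16.3,3.27,0.38
lr_gre_pd,134.2,57.8,484.2,298.6,35.2,16.5,1.14,0.22
lr_gre_t1,153.7,68.8,484.2,298.6,39.1,16.1,3.36,0.68
lr_se_t1,207.3,109.4,484.2,298.6,47.8,11.6,2.91,0.63
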