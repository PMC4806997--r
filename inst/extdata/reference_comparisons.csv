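dataset,reference,mean_diff_pct_fgt,pearson_r
hr_gre_t1,hr_gre_pd,2.9,0.995
lr_gre_pd,hr_gre_pd,-1.1,0.99
lr_gre_t1,lr_gre_pd,3.9,0.99
lr_se_t1,lr_gre_pd,12.6,0.96
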