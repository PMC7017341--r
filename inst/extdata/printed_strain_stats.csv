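strain,length_um_mean,length_um_sd,dev_bestfit_mean,dev_bestfit_sd,dev_slope1_mean,dev_slope1_sd
wt,9.9,2.9,0.03,0.07,-0.03,0.16
lf1,17.9,2.5,0.24,0.14,0.25,0.14
lf2-1,16.7,4.3,0.18,0.12,0.19,0.11
lf4,19.9,8.4,0.22,0.18,0.23,0.17
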