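module,variable,n_asd,mean_asd,sd_asd,n_cc,mean_cc,sd_cc
3,age,37,11.35,2.79,27,10.68,2.74
3,full_scale_iq,33,92.09,20.87,20,103.55,17.05
3,verbal_iq,33,93.39,21.19,20,104.50,18.02
3,ados_sa,37,10.05,2.89,27,5.37,3.65
3,ados_rrb,37,1.27,1.54,27,0.26,0.59
3,adir_a,36,17.58,6.38,24,6.25,5.53
3,adir_b,36,13.00,4.67,24,4.58,4.09
3,adir_c,36,4.81,2.62,24,1.12,1.39
4,age,19,18.26,3.05,11,19.69,4.18
4,full_scale_iq,18,95.56,17.52,8,77.25,12.34
4,verbal_iq,17,102.65,19.20,8,90.25,11.12
4,ados_sa,19,10.74,4.11,11,5.82,3.95
4,ados_rrb,19,2.05,1.75,11,0.73,1.01
4,adir_a,16,14.31,7.91,8,6.50,4.87
4,adir_b,16,10.44,4.70,8,4.88,3.80
4,adir_c,16,4.81,2.61,8,1.75,1.49
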