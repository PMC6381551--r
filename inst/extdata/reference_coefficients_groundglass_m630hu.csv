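feature,constant,thickness_2.5,thickness_1.25,mas_120,kernel_standard,sig_thickness_2.5,sig_thickness_1.25,sig_mas_120,sig_kernel_standard
hist_mean,0.617,0.247,0.277,-0.011,-0.154,1,1,0,1
hist_stddev,0.369,0.036,0.158,-0.149,-0.279,0,1,1,1
hist_variance,0.230,0.034,0.154,-0.125,-0.200,0,1,1,1
hist_skewness,-0.023,0.209,0.256,0.143,0.224,1,1,1,1
hist_kurtosis,0.985,-0.146,-0.098,-0.149,-0.436,1,1,1,1
hist_energy,0.061,0.063,-0.021,0.189,0.361,1,0,1,1
hist_entropy,0.664,0.014,0.122,-0.196,-0.394,0,1,1,1
glcm_contrast,0.237,0.111,0.238,-0.108,-0.206,1,1,1,1
glcm_dissimilarity,0.349,0.121,0.251,-0.141,-0.292,1,1,1,1
glcm_homogeneity,0.193,-0.039,-0.154,0.191,0.422,1,1,1,1
glcm_asm,0.027,-0.004,-0.060,0.109,0.166,0,1,1,1
glcm_energy,0.080,-0.015,-0.086,0.139,0.233,0,1,1,1
glcm_probability_max,0.052,-0.008,-0.036,0.084,0.122,0,1,1,1
glcm_entropy,0.788,0.042,0.130,-0.153,-0.284,0,1,1,1
glcm_correlation,0.752,-0.100,-0.228,0.109,0.204,1,1,1,1
glrlm_lre,0.068,0.014,-0.054,0.130,0.258,0,1,1,1
glrlm_gln,0.033,0.033,-0.018,0.125,0.223,1,0,1,1
glrlm_rln,0.891,-0.004,0.078,-0.163,-0.318,0,1,1,1
glrlm_lgre,0.167,-0.106,-0.086,-0.018,0.011,1,1,0,0
glrlm_hgre,0.639,0.227,0.269,-0.030,-0.144,1,1,1,1
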