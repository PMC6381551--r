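feature,constant,thickness_2.5,thickness_1.25,mas_120,kernel_standard,sig_thickness_2.5,sig_thickness_1.25,sig_mas_120,sig_kernel_standard
hist_mean,0.323,0.418,0.613,0.020,-0.271,1,1,1,1
hist_stddev,0.442,-0.085,-0.237,-0.055,-0.075,1,1,1,1
hist_variance,0.260,-0.058,-0.152,-0.036,-0.047,1,1,1,1
hist_skewness,0.008,0.179,0.463,0.051,0.108,1,1,1,1
hist_kurtosis,0.772,-0.135,-0.177,-0.032,-0.234,1,1,0,1
hist_energy,0.112,0.388,0.642,0.103,-0.209,1,1,1,1
hist_entropy,0.814,-0.430,-0.664,-0.079,0.188,1,1,1,1
glcm_contrast,0.078,0.171,0.383,-0.022,-0.026,1,1,1,1
glcm_dissimilarity,0.231,0.011,0.135,-0.058,0.036,0,1,1,1
glcm_homogeneity,0.147,0.472,0.600,0.131,-0.127,1,1,1,1
glcm_asm,0.025,0.387,0.552,0.186,-0.159,1,1,1,1
glcm_energy,0.130,0.476,0.614,0.142,-0.145,1,1,1,1
glcm_probability_max,0.150,0.466,0.583,0.141,-0.137,1,1,1,1
glcm_entropy,0.856,-0.454,-0.646,-0.116,0.153,1,1,1,1
glcm_correlation,0.927,-0.129,-0.299,0.026,0.015,1,1,1,0
glrlm_lre,0.036,0.452,0.574,0.178,-0.097,1,1,1,1
glrlm_gln,0.105,0.418,0.621,0.117,-0.181,1,1,1,1
glrlm_rln,0.745,-0.541,-0.636,-0.105,0.116,1,1,1,1
glrlm_lgre,0.212,-0.130,-0.180,-0.011,0.037,1,1,0,1
glrlm_hgre,0.288,0.509,0.672,0.039,-0.161,1,1,1,1
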