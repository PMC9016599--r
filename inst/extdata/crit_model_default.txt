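# entsat critical-value model
intercept 31.078295851463981
coef_sqrt_taxa 5.3120232553551876
coef_sqrt_len -1.4483804071986086
adjusted_r2 0.64470862521042305
taxa_min 8
taxa_max 128
len_min 250
len_max 1250
bin 8 375 5.5145122186822961 0.60869565217391308 0.065573770491803282 84
bin 8 625 5.1549738422766866 0.44444444444444442 0.012658227848101266 97
bin 8 875 5.3996510819233983 0.38461538461538464 0.036585365853658534 95
bin 8 1125 5.3761788055029252 0.27272727272727271 0 107
bin 32 375 26.937574486667828 0.98863636363636365 0.91304347826086951 111
bin 32 625 20.933180996121511 0.80597014925373134 0.44 92
bin 32 875 24.263958105168896 0.84615384615384615 0.5 105
bin 32 1125 27.622905024357046 0.94736842105263153 0.48484848484848486 90
bin 128 375 92.879047678519356 0.98809523809523814 1 95
bin 128 625 51.844648989533461 0.97894736842105268 0.93333333333333335 110
bin 128 875 26.148053178293001 0.93975903614457834 0.66666666666666663 116
bin 128 1125 34.512338057392242 0.92000000000000004 0.56521739130434778 98
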