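sample,GPx,SMT,SELENOP,SELENOW_plus_others,SeAlb,sum_of_species
sample_1,2.73,3.70,50.78,31.37,1.92,90.51
sample_2,3.01,3.80,60.84,37.77,2.34,107.76
sample_3,3.47,6.88,70.00,24.64,1.69,106.67
sample_4,3.50,2.22,63.93,30.59,1.90,102.14
sample_5,3.51,4.09,78.80,24.89,1.37,112.66
sample_6,3.58,4.66,81.42,34.68,2.46,126.81
sample_7,3.60,5.28,46.96,34.21,1.89,91.93
sample_8,3.66,1.94,53.77,33.40,1.80,94.57
sample_9,3.69,4.79,37.20,38.64,2.18,86.50
sample_10,3.80,3.57,63.31,44.27,2.48,117.44
sample_11,3.83,2.27,46.62,40.18,2.70,95.60
sample_12,3.88,6.77,46.96,35.69,1.90,95.20
sample_13,3.89,3.06,68.38,33.75,2.49,111.57
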