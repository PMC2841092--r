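sex,ethnicity,age,k,theta,mean_shifted,sd_shifted,k_shifted,theta_shifted
men,white,all,0.436,48.132,40.268,47.275,0.726,55.501
men,white,18-34,0.450,58.550,50.586,59.388,0.726,69.721
men,white,35-54,0.441,46.951,38.993,45.778,0.726,53.743
men,white,55+,0.430,37.486,29.713,34.883,0.726,40.953
men,black,all,0.387,65.821,49.570,58.195,0.726,68.321
men,black,18-34,0.380,65.850,47.957,56.301,0.726,66.098
men,black,35-54,0.406,65.155,52.860,62.058,0.726,72.856
men,black,55+,0.362,66.530,44.642,52.410,0.726,61.529
men,native,all,0.354,88.399,56.528,66.363,0.726,77.911
men,native,18-34,0.354,111.130,70.687,82.987,0.726,97.427
men,native,35-54,0.376,87.400,58.111,68.223,0.726,80.094
men,native,55+,0.345,46.584,27.412,32.181,0.726,37.781
men,asian,all,0.417,28.224,22.544,26.467,0.726,31.072
men,asian,18-34,0.460,27.784,26.022,30.549,0.726,35.865
men,asian,35-54,0.412,30.006,22.784,26.749,0.726,31.403
men,asian,55+,0.345,17.665,11.801,13.854,0.726,16.265
men,hispanic,all,0.426,40.756,40.726,47.812,0.726,56.131
men,hispanic,18-34,0.422,43.417,36.148,42.438,0.726,49.823
men,hispanic,35-54,0.433,40.633,52.215,61.300,0.726,71.967
men,hispanic,55+,0.426,31.678,23.517,27.609,0.726,32.413
women,white,all,0.391,19.778,14.785,18.361,0.648,22.801
women,white,18-34,0.399,23.009,17.353,21.376,0.659,26.330
women,white,35-54,0.410,18.282,14.224,17.702,0.646,22.030
women,white,55+,0.366,17.852,12.495,15.672,0.636,19.657
women,black,all,0.316,27.729,20.069,24.565,0.668,30.066
women,black,18-34,0.311,30.996,19.844,24.299,0.667,29.756
women,black,35-54,0.326,27.461,22.642,27.585,0.674,33.607
women,black,55+,0.310,19.494,12.313,15.459,0.634,19.408
women,native,all,0.295,54.514,33.405,40.221,0.690,48.427
women,native,18-34,0.297,87.190,49.135,58.688,0.701,70.098
women,native,35-54,0.304,42.472,27.347,33.109,0.682,40.084
women,native,55+,0.336,20.350,19.866,24.326,0.667,29.787
women,asian,all,0.318,24.855,14.464,17.984,0.647,22.360
women,asian,18-34,0.311,42.172,24.428,29.682,0.677,36.065
women,asian,35-54,0.441,6.702,5.460,7.413,0.542,10.065
women,asian,55+,0.360,5.835,2.430,3.856,0.397,6.118
women,hispanic,all,0.341,17.855,18.482,22.701,0.663,27.883
women,hispanic,18-34,0.325,23.545,15.423,19.109,0.651,23.677
women,hispanic,35-54,0.377,12.815,24.680,29.977,0.678,36.411
women,hispanic,55+,0.330,13.513,10.682,13.544,0.622,17.173
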