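cluster,intercept,intercept_se,malignancy,malignancy_se,calf_difference,calf_difference_se,surgery,surgery_se
1,-2.46,0.14,0.90,0.33,1.17,0.19,0.04,0.35
2,-0.95,0.11,0.31,0.24,0.98,0.15,0.17,0.25
3,-2.92,0.44,1.57,0.87,1.59,0.50,1.73,0.54
4,-1.92,0.09,0.63,0.16,1.68,0.13,0.83,0.17
5,-2.27,0.16,0.24,0.42,1.03,0.20,0.52,0.26
6,-2.25,0.12,1.23,0.30,1.40,0.17,0.51,0.21
7,-3.18,0.13,1.69,0.22,1.41,0.19,0.26,0.31
8,-1.72,0.18,1.02,0.58,1.24,0.27,0.78,0.51
9,-2.01,0.11,0.80,0.25,1.25,0.14,0.37,0.19
10,-2.16,0.18,1.04,0.46,0.65,0.34,0.79,0.35
11,-2.30,0.19,1.65,0.26,1.32,0.23,0.82,0.27
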