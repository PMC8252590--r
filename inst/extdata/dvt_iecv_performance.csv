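cluster,cal_slope,cal_slope_se,cal_in_large,cal_in_large_se,c_statistic,c_statistic_se
1,0.86,0.15,-0.44,0.10,0.65,0.02
2,0.63,0.11,1.06,0.08,0.63,0.02
3,1.49,0.35,-0.24,0.22,0.78,0.05
4,1.18,0.10,0.43,0.06,0.72,0.01
5,0.73,0.15,-0.33,0.10,0.65,0.02
6,1.12,0.14,0.00,0.08,0.70,0.02
7,1.24,0.14,-0.93,0.09,0.71,0.02
8,1.02,0.24,0.51,0.13,0.67,0.03
9,0.92,0.11,0.12,0.07,0.68,0.02
10,0.71,0.27,-0.09,0.14,0.62,0.04
11,1.27,0.17,0.15,0.11,0.74,0.03
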