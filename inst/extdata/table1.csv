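subject,cf,f_p_hz,q10_stc,q10_ptc
1,1000,1120,4.76,4.57
2,1000,960,4.29,5.14
3,1000,1120,4.65,4.03
4,1000,1080,4.81,5.51
5,1000,960,3.22,5.52
6,1000,960,4.55,4.66
7,1000,1060,7.11,5.79
8,1000,960,4.46,5.25
9,1000,960,3.01,5.33
10,1000,1000,4.50,5.76
1,2000,1800,4.40,8.01
2,2000,2080,3.66,4.29
3,2000,2200,5.38,5.58
4,2000,2040,3.69,4.71
5,2000,1800,5.06,6.51
6,2000,2040,4.20,4.53
7,2000,2160,5.00,3.64
8,2000,1800,4.86,6.21
9,2000,2040,4.30,3.57
10,2000,1800,4.04,4.86
1,4000,4200,6.45,6.88
2,4000,3960,6.36,5.16
3,4000,3840,7.43,6.60
4,4000,3840,4.90,6.40
5,4000,3840,5.31,6.76
6,4000,3840,7.11,5.64
7,4000,3840,6.45,7.49
8,4000,3800,6.01,6.80
9,4000,3800,6.26,5.72
10,4000,3960,5.79,6.92
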