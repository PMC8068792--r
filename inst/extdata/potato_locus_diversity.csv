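locus,Na,Ng,H,GD,Evenness
STG0001,13,42,1.84,0.80,0.77
STM0019ab,20,60,2.00,0.83,0.78
STG0010,8,17,1.24,0.66,0.80
STM0031,18,51,1.85,0.79,0.70
STG0016,17,53,1.78,0.80,0.80
STM0037,14,51,1.81,0.79,0.74
STG0025,6,9,0.82,0.52,0.86
STM1052,13,48,1.66,0.76,0.76
STI0001,9,29,1.61,0.77,0.85
STM1053,5,6,0.39,0.18,0.46
STI0003,16,43,1.78,0.80,0.83
STM1064,6,11,1.07,0.59,0.75
STI0004,9,34,1.51,0.73,0.77
STM1104,6,15,1.18,0.63,0.74
STI0012,13,36,1.63,0.76,0.76
STM1106,15,26,1.30,0.61,0.57
STI0014,7,15,1.18,0.65,0.81
STM5114,11,22,1.62,0.76,0.78
STI0030,10,31,1.41,0.70,0.75
STM5121,4,8,0.85,0.50,0.73
STI0032,9,27,1.75,0.81,0.91
STM5127,9,41,1.73,0.78,0.77
STI0033,10,33,1.62,0.77,0.81
STPoAc58,9,19,0.80,0.38,0.49
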