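population,YN,TD,LA,LZ,LC,FC,QN,YH,XD,ST,HZ,LN
YN,NA,4.750,4.214,1.154,1.187,1.170,0.851,0.730,2.955,3.128,2.023,2.955
TD,0.050,NA,14.456,1.395,1.428,1.139,0.886,0.846,3.271,2.875,1.734,2.591
LA,0.056,0.017,NA,2.382,2.559,1.274,1.080,0.946,4.295,3.039,1.575,2.023
LZ,0.178,0.152,0.095,NA,11.655,0.897,0.897,1.032,1.486,1.212,0.708,0.818
LC,0.174,0.149,0.089,0.021,NA,0.861,0.902,0.982,1.658,1.332,0.742,0.823
FC,0.176,0.180,0.164,0.218,0.225,NA,0.861,0.549,1.045,0.975,0.719,0.814
QN,0.227,0.220,0.188,0.218,0.217,0.225,NA,0.361,0.775,1.059,0.597,0.666
YH,0.255,0.228,0.209,0.195,0.203,0.313,0.409,NA,0.935,0.754,0.485,0.494
XD,0.078,0.071,0.055,0.144,0.131,0.193,0.244,0.211,NA,2.915,1.428,1.474
ST,0.074,0.080,0.076,0.171,0.158,0.204,0.191,0.249,0.079,NA,1.943,1.549
HZ,0.110,0.126,0.137,0.261,0.252,0.258,0.295,0.340,0.149,0.114,NA,1.256
LN,0.078,0.088,0.110,0.234,0.233,0.235,0.273,0.336,0.145,0.139,0.166,NA
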