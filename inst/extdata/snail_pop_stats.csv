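population,Na,Ne,I,Ho,He,F
YN,6.333,3.437,1.417,0.530,0.684,0.227
TD,6.111,3.921,1.464,0.599,0.723,0.173
LA,6.667,4.405,1.564,0.520,0.749,0.311
LZ,6.333,2.761,1.178,0.522,0.560,0.073
LC,5.444,2.498,1.093,0.414,0.536,0.273
FC,3.000,1.888,0.736,0.407,0.441,0.078
QN,4.778,1.869,0.795,0.373,0.390,0.028
YH,3.222,1.663,0.552,0.285,0.299,0.054
XD,5.556,3.041,1.230,0.518,0.627,0.177
ST,5.111,3.472,1.328,0.635,0.672,0.068
HZ,3.556,2.309,0.945,0.424,0.530,0.190
LN,4.333,2.757,1.093,0.530,0.598,0.126
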