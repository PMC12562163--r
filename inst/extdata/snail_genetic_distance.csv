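population,YN,TD,LA,LZ,LC,FC,QN,YH,XD,ST,HZ,LN
YN,0,0.657,0.719,0.381,0.363,0.593,0.486,0.494,0.364,0.413,0.673,0.709
TD,0.657,0,0.328,0.570,0.648,0.523,0.614,0.691,0.440,0.394,0.303,0.258
LA,0.719,0.328,0,0.637,0.672,0.612,0.639,0.673,0.455,0.431,0.418,0.398
LZ,0.381,0.570,0.637,0,0.145,0.526,0.533,0.424,0.344,0.516,0.645,0.641
LC,0.363,0.648,0.672,0.145,0,0.523,0.488,0.381,0.372,0.516,0.630,0.629
FC,0.593,0.523,0.612,0.526,0.523,0,0.439,0.569,0.515,0.535,0.627,0.597
QN,0.486,0.614,0.639,0.533,0.488,0.439,0,0.652,0.558,0.467,0.684,0.664
YH,0.494,0.691,0.673,0.424,0.381,0.569,0.652,0,0.430,0.630,0.722,0.733
XD,0.364,0.440,0.455,0.344,0.372,0.515,0.558,0.430,0,0.349,0.511,0.526
ST,0.413,0.394,0.431,0.516,0.516,0.535,0.467,0.630,0.349,0,0.343,0.456
HZ,0.673,0.303,0.418,0.645,0.630,0.627,0.684,0.722,0.511,0.343,0,0.384
LN,0.709,0.258,0.398,0.641,0.629,0.597,0.664,0.733,0.526,0.456,0.384,0
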