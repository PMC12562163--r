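locus,Na,Ne,I,Ho,He,F,Hs,PIC
DLJL017,10,3.848,1.649,0.484,0.74,0.346,0.87,0.702
DLJL021,12,4.739,1.76,0.417,0.789,0.472,0.894,0.759
DLJL025,9,3.658,1.591,0.474,0.727,0.348,0.863,0.697
DLJL033,11,6.285,2.043,0.537,0.841,0.362,0.92,0.823
DLJL042,5,3.388,1.391,0.356,0.705,0.496,0.852,0.662
DLJL095,24,7.856,2.371,0.42,0.873,0.519,0.936,0.861
DLJL112,15,3.788,1.732,0.494,0.736,0.328,0.868,0.71
DLJL125,18,7.495,2.277,0.598,0.867,0.310,0.933,0.853
DLJL126,15,5.121,1.987,0.537,0.805,0.332,0.902,0.783
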