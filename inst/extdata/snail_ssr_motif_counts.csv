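motif,type,n
A,mono,235187
AC,di,212705
AAT,tri,27379
AGAT,tetra,34416
AATAT,penta,293
AAGAAT,hexa,69
ACACAG,hexa,72
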