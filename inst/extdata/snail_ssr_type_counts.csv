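type,n,pct,avg_len,n_motif_types
mono,266097,33.34,11.26,4
di,380290,47.64,17.67,6
tri,74729,9.36,19.62,20
tetra,75213,9.42,58.45,56
penta,1604,0.20,56.37,82
hexa,311,0.04,43.98,36
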