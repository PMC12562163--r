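source,df,SS,MS,variance_component,pct
Among Pops,11,685.560,62.324,0.984,27
Within Pops,708,1902.700,5.395,2.697,73
Total,719,2588.260,67.719,3.681,100
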