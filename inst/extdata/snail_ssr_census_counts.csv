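field,value
n_sequences_examined,7042688
total_bp,1657747000
n_ssr,798244
n_compound_member_ssr,126494
n_sequences_with_ssr,664946
n_sequences_with_multiple_ssr,108342
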