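classifier,tn,tp,fn,fp
asd_vs_cc,19,43,13,19
ndd_vs_cc,10,46,28,10
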