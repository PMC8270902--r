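approach,sd,ud,ns
one_step,3,5,2
two_step,5,0,5
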