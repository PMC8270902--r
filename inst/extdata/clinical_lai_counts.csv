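metric,sld,ald,n_patients
FA,5,10,25
MD,2,4,25
MK,10,10,25
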