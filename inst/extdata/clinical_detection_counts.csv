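method,sd,ud,ns
FA,5,19,1
MD,7,16,2
MK,5,19,1
MD_MK,7,8,10
MD_FA,9,5,11
FA_MK,6,11,8
iDrArK,8,1,16
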