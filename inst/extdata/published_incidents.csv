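species,count
humpback,457
minke,391
fin,102
na_right,68
blue,27
sei,14
unidentified,51
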