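species,count
humpback,263261
na_right,71772
minke,67048
fin,60924
blue,11390
sei,8608
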