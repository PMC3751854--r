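rater_a,Normal,III,IV-V,VI,VII,VIII
Normal,10,4,0,0,0,0
III,1,6,0,0,0,0
IV-V,0,1,7,1,0,1
VI,0,0,0,2,0,0
VII,0,0,1,0,2,0
VIII,0,0,0,0,0,1
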