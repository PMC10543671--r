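true_class,Blank,NoCrystal,Weak,Good,Strong
Blank,2069,0,0,0,0
NoCrystal,2,3266,0,0,0
Weak,3,24,3273,46,0
Good,0,0,62,2341,41
Strong,0,0,0,60,1412
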