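label,p1,p2,role
1.1,0.20,0.20,global_null
1.2,0.40,0.40,global_alternative
1.3,0.40,0.45,HA_star
1.4,0.40,0.60,HA_plus
1.5,0.20,0.40,other
1.6,0.40,0.70,other
1.7,0.40,0.43,other
1.8,0.45,0.40,other
1.9,0.60,0.40,other
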