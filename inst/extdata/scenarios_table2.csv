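label,q1,p1,q2,p2
2.1,0.40,0.20,0.40,0.20
2.2,0.25,0.40,0.25,0.40
2.3,0.25,0.40,0.25,0.60
2.4,0.25,0.40,0.25,0.45
2.5,0.30,0.20,0.35,0.20
2.6,0.40,0.25,0.50,0.30
2.7,0.15,0.20,0.20,0.40
2.8,0.15,0.40,0.20,0.65
2.9,0.15,0.50,0.20,0.75
2.10,0.20,0.40,0.40,0.60
2.11,0.15,0.40,0.20,0.45
2.12,0.05,0.40,0.20,0.50
2.13,0.05,0.50,0.20,0.60
2.14,0.20,0.50,0.45,0.40
2.15,0.15,0.50,0.20,0.45
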