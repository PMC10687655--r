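age,annual_death_probability
65,0.01647
66,0.01791
67,0.01953
68,0.02134
69,0.02334
70,0.02554
71,0.02790
72,0.03047
73,0.03342
74,0.03682
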