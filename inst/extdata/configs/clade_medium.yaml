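# Clade initiation, medium start (u0 = 4)
scenario: clade_initiation
u0: 4
x0: 10
seed: 1
t_end: 1200
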