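# Clade initiation, close start (u0 = 0.5)
scenario: clade_initiation
u0: 0.5
x0: 10
seed: 1
t_end: 1200
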