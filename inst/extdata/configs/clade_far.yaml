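# Clade initiation, far start (u0 = 10)
scenario: clade_initiation
u0: 10
x0: 10
seed: 1
t_end: 1200
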