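# Evolutionary rescue: peak steps 0 -> -4 at t = 600 (medium start)
scenario: rescue
u0: 4
x0: 10
seed: 1
t_end: 3000
env: {mode: step, gamma0: 0, times: [600], gammas: [-4]}
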