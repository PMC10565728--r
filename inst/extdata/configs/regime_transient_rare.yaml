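# Transient disturbance: peak to -4.4 at 900, reverting to 0 at 2000
scenario: disturbance_regime
u0: 4
x0: 10
seed: 1
t_end: 2500
env: {mode: step, gamma0: 0, times: [900, 2000], gammas: [-4.4, 0]}
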