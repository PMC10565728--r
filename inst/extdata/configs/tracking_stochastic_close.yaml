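# Stochastic evolutionary tracking, close start: peak redrawn U(-2,2) every 5 time units
scenario: tracking_stochastic
u0: 0.5
x0: 10
n_trials: 100
seed: 1
t_end: 600
env: {mode: stochastic, gamma0: 0, redraw_interval: 5, redraw_bounds: [-2, 2]}
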