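# Deterministic (sinusoidal) evolutionary tracking, close start: gamma(t) = sin(t/50)
scenario: tracking_deterministic
u0: 0.5
x0: 10
seed: 1
t_end: 1200
env: {mode: sinusoidal, amplitude: 1, period: 50}
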