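# Periodic disturbance train (qualitative fixture): the exact period of the
# repeating schedule is a free choice; half-periods of ~900 time units sit in
# the transient-coexistence window.  Edit times/gammas to explore.
scenario: disturbance_regime
u0: 4
x0: 10
seed: 1
t_end: 4500
env:
  mode: step
  gamma0: 0
  times: [900, 1800, 2700, 3600]
  gammas: [-4.4, 0, -4.4, 0]
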