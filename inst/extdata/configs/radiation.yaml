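# Adaptive radiation: bounded competition kernel, sigma_a2 = 2
scenario: adaptive_radiation
u0: 0.5
x0: 10
seed: 1
t_end: 1500
max_species: 12
params:
  sigma_a2: 2
  kernel: bounded
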