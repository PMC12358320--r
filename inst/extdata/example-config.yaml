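# Example configuration: near-perfect transmission, fixed fitness benefit,
# no cytoplasmic incompatibility, standard batch protocol.
population:
  N: 10000
  sh: 0.0
transmission:
  groups:
    - fraction: 0.9
      mu: 0.001
    - fraction: 0.1
      mu: 0.8
fitness:
  mode: fixed
  median: 1.1
  cv: 0.0
protocol:
  p0: 0.4
  generations: 10000
  burn_in: 500
  n_reps: 25
  base_seed: 42
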