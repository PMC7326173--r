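# Baseline simulation scenario of the green-technology innovation game.
# Note: this parameter set violates the R = N * R_star identity of the
# model text (R = 1000 but N * R_star = 10000); it is kept as published
# and loading it warns accordingly.
econ:
  "N": 100
  C1: 2
  a: 0.4
  b: 0.7
  R: 1000
  R_star: 100
  C: 100
  P_success: 0.4
  T: 85
  mu: 1.297
  r: 0.015
  t1: 100
  t2: 300
moran:
  u: 0.5
  fitness_map: linear
  fitness_floor: 1.0e-9
simulate:
  mutation_rate: 0.01
  replicates: 1000
  max_steps: 1000000
  start: 1
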