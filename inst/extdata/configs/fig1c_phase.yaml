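# Phase-diagram grid in (delta0_ii, delta0_ee) at K = 1000, I0_e = 0.1.
model:
  I0_e: 0.1
  I0_i: 0.09803921568627451
  delta0_ee: 1.5
  delta0_ii: 0.3
  K: 1000
run:
  dt: 0.01
  T: 30000
  transient: 10000
scan:
  control: delta0_ii
  from: 0.05
  to: 1.5
  n_points: 8
analysis:
  task: scan_regimes
seeds:
  connectivity: 1
  init: 1
  tangent: 1
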