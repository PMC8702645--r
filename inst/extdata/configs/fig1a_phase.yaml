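# Phase-diagram grid in (I0_e, delta0_ee) at K = 1000, delta0_ii = 0.3.
model:
  I0_e: 0.01
  I0_i: 0.00980392156862745
  delta0_ee: 2.0
  delta0_ii: 0.3
  K: 1000
run:
  dt: 0.01
  T: 30000
  transient: 10000
scan:
  control: I0
  from: 1.0e-4
  to: 100
  n_points: 13
  log: true
analysis:
  task: scan_regimes
seeds:
  connectivity: 1
  init: 1
  tangent: 1
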