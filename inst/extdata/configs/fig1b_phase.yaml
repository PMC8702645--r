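# Phase-diagram grid in (K, delta0_ee) at I0_e = 0.001, delta0_ii = 0.3.
model:
  I0_e: 0.001
  I0_i: 0.000980392156862745
  delta0_ee: 2.0
  delta0_ii: 0.3
  K: 1000
run:
  dt: 0.01
  T: 30000
  transient: 10000
scan:
  control: K
  values: [100, 300, 1000, 3000, 10000]
analysis:
  task: scan_regimes
seeds:
  connectivity: 1
  init: 1
  tangent: 1
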