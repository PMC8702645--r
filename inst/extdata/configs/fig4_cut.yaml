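# Period-doubling route to collective chaos: cut through the phase diagram
# at fixed heterogeneities, scanning the excitatory DC current.
model:
  I0_e: 0.001
  I0_i: 0.000980392156862745
  delta0_ee: 2.0
  delta0_ii: 0.3
  K: 1000
run:
  dt: 0.01
  T: 60000
  transient: 20000
scan:
  control: I0
  from: 1.0e-4
  to: 2.0e-3
  n_points: 20
  log: true
analysis:
  task: scan_peaks
seeds:
  connectivity: 1
  init: 1
  tangent: 1
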