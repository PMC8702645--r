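# Scaling of periodic collective-oscillation frequencies with I0_e and K
# (limit-cycle states of the neural mass model).
model:
  I0_e: 0.0009
  I0_i: 0.0008823529411764706
  delta0_ee: 2.0
  delta0_ii: 0.3
  K: 1000
run:
  dt: 0.01
  T: 40000
  transient: 15000
scan:
  control: K
  values: [300, 1000, 3000]
analysis:
  task: scan_peaks
seeds:
  connectivity: 1
  init: 1
  tangent: 1
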