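# Fluctuation-driven to abnormally synchronized oscillations: cut at
# delta0_ee = 1.58 scanning the excitatory DC current through the
# subcritical Hopf bifurcation.
model:
  I0_e: 1.0
  I0_i: 0.9803921568627451
  delta0_ee: 1.58
  delta0_ii: 0.3
  K: 1000
run:
  dt: 0.01
  T: 50000
  transient: 10000
scan:
  control: I0
  from: 10
  to: 100
  n_points: 2
analysis:
  task: hopf
seeds:
  connectivity: 1
  init: 1
  tangent: 1
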