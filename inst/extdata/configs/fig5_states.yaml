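# The three marked states on the period-doubling cut: chaotic
# (I0_e = 0.00021), periodic (0.0009) and stable focus (0.006); network
# simulation settings at desk scale.
model:
  I0_e: 0.0009
  I0_i: 0.0008823529411764706
  delta0_ee: 2.0
  delta0_ii: 0.3
  K: 256
run:
  dt: 0.001
  T: 20000
  transient: 2000
  N_e: 2500
  N_i: 625
analysis:
  task: network
seeds:
  connectivity: 1
  init: 1
  tangent: 1
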