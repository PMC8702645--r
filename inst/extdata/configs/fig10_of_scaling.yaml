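# Scaling of the fluctuation-driven oscillation frequencies with I0_e
# (relaxation frequencies of the stable focus).
model:
  I0_e: 0.001
  I0_i: 0.000980392156862745
  delta0_ee: 1.3
  delta0_ii: 0.3
  K: 1000
analysis:
  task: eigen
seeds:
  connectivity: 1
  init: 1
  tangent: 1
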