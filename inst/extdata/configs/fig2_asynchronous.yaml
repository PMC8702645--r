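# Asynchronous balanced regime: rates, effective currents and fluctuations
# versus the median in-degree K.
model:
  I0_e: 0.2
  I0_i: 0.19607843137254902   # I0_e / 1.02
  delta0_ee: 2.5
  delta0_ii: 1.0
  K: 1000
scan:
  control: K
  values: [16, 32, 64, 128, 256, 512, 1024, 2048, 4096, 8192, 16384]
analysis:
  task: fixed_point
seeds:
  connectivity: 1
  init: 1
  tangent: 1
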