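# Coherence and CV of the whole network across the subcritical Hopf
# (desk-scale network sizes).
model:
  I0_e: 0.128
  I0_i: 0.12549019607843137
  delta0_ee: 1.58
  delta0_ii: 0.3
  K: 256
run:
  dt: 0.001
  T: 10000
  transient: 2000
  N_e: 2500
  N_i: 625
  record_v_stride: 1
analysis:
  task: network
seeds:
  connectivity: 1
  init: 1
  tangent: 1
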