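# Quasi-periodicity and frequency locking of fluctuation-driven
# oscillations: stable-focus relaxation frequencies from the eigenvalues.
model:
  I0_e: 0.128
  I0_i: 0.12549019607843137
  delta0_ee: 1.58
  delta0_ii: 0.3
  K: 8192
analysis:
  task: eigen
seeds:
  connectivity: 1
  init: 1
  tangent: 1
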