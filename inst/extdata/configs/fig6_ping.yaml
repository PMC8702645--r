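# PING-like delay between excitatory and inhibitory bursts in the
# oscillatory regime (inhibitory membrane time constant is the control).
model:
  I0_e: 0.0009
  I0_i: 0.0008823529411764706
  delta0_ee: 2.0
  delta0_ii: 0.3
  K: 1000
  tau_m_e: 20
  tau_m_i: 20
run:
  dt: 0.01
  T: 20000
  transient: 10000
analysis:
  task: ping_delay
seeds:
  connectivity: 1
  init: 1
  tangent: 1
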