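# Starvation-induced producer, single pseudo-starving induction:
# batch, growth at mu 0.15 1/h to 70 g/L DCW, then a constant feed
# sized for q_S 0.005 g/g/h.
strain: PDH-PS
strategy: PS
promoter_mode: starvation_induced
seed: 1
dt_out: 0.25
feed:
  mu_set: 0.15             # 1/h, growth phase
  q_S_set: 0.005           # g/g/h, induction phase
  X_stop: 70               # g DCW/L at induction start
  induction_hours: 40      # h
  S_feed: 400              # g/L
  V0: 2
  X0: 0.5
  S0: 40
kinetics:
  mu_max: 0.20
  K_S: 0.1
  Y_XS: 0.58
  m_S: 0
product:
  q_p_max: 12.5            # AU/g/h peak induced rate
  q_S_rep: 0.02            # g/g/h repression threshold
  tau: 12                  # h induction decay constant
noise:
  rsd_dcw: 0.05
  rsd_hplc: 0.01
  rsd_gas: 0.05
  rsd_activity: 0.04
output: {}
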