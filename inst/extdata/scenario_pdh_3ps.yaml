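# Starvation-induced producer, three growth/induction cycles:
# growth at mu 0.15 1/h to 40, 60, 80 g/L DCW, each followed by a 24 h
# pseudo-starving induction at q_S 0.005 g/g/h.
strain: PDH-3PS
strategy: 3-PS
promoter_mode: starvation_induced
seed: 1
dt_out: 0.25
feed:
  mu_set: 0.15
  q_S_set: 0.005
  X_stop: [40, 60, 80]     # g DCW/L cycle targets
  induction_hours: 24      # h per induction
  S_feed: 400
  V0: 2
  X0: 0.5
  S0: 40
kinetics:
  mu_max: 0.20
  K_S: 0.1
  Y_XS: 0.58
  m_S: 0
product:
  q_p_max: 12.5
  q_S_rep: 0.02
  tau: 12
noise:
  rsd_dcw: 0.05
  rsd_hplc: 0.01
  rsd_gas: 0.05
  rsd_activity: 0.04
output: {}
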