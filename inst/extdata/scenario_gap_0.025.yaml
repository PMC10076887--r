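# Constitutive (growth-coupled) producer, carbon-limited fed-batch at
# low constant mu. All tunables surfaced; units in comments.
strain: GAP-0.025
strategy: FB-mu            # batch + exponential constant-mu feed
promoter_mode: growth_coupled
seed: 1
dt_out: 0.25               # output sampling interval, h
feed:
  mu_set: 0.025            # 1/h
  X_stop: 80               # g DCW/L, feed stops here
  S_feed: 400              # g/L glycerol in feed
  V0: 2                    # L
  X0: 0.5                  # g DCW/L after inoculation
  S0: 40                   # g/L batch glycerol
kinetics:
  mu_max: 0.20             # 1/h, on glycerol
  K_S: 0.1                 # g/L
  Y_XS: 0.54               # g DCW / g glycerol
  m_S: 0                   # g/g/h maintenance
product:
  alpha: 100.45            # AU/g DCW (= Y_P/X)
noise:
  rsd_dcw: 0.05
  rsd_hplc: 0.01
  rsd_gas: 0.05
  rsd_activity: 0.04
output: {}
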