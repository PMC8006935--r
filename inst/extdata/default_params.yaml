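# Default model configuration.
#
# Growth parameters: chosen so that (i) the resistant steady state exceeds
# the sensitive steady state, (ii) all four populations reach steady state
# well within 300 h, with per-hour rates on the scale typical of glioma
# cell-line doubling times (20-40 h).
#
# Drug-effect parameters: ic50 values are the measured cell-line potencies
# (TMZ 190 uM resistant / 23.33 uM sensitive; AC26 0.76/0.9; AC2 1.53/1.53;
# AC7 1.05/5.67).  emax and the Hill exponents were calibrated once so that
# simulated 72-h monotherapy dose-response curves cross 50% relative growth
# near the configured ic50 of the corresponding compartment.
growth:
  alpha_N: 0.06      # per hour
  delta_N: 0.012     # per hour
  rho: 0.01          # mutation probability N -> C
  K: 1.0e+6          # shared carrying capacity (cells)
  mu: 1.0            # Gompertz offset (cells)
  alpha_C: 0.048     # per hour
  delta_C: 0.012     # per hour
  gamma_R: 0.6       # differentiation probability C -> C_R
  omega_S: 0.4       # differentiation probability C -> C_S (1 - gamma_R)
  gamma_R_tilde: 0.1 # switching probability C_S -> C_R (forward)
  omega_S_tilde: 0.05  # switching probability C_R -> C_S (backward)
  alpha_CR: 0.06     # per hour
  delta_R: 0.0096     # per hour
  alpha_CS: 0.048     # per hour
  delta_S: 0.0144     # per hour
initial_state:
  "N": 1.0e+5   # quoted: a bare N is YAML-1.1 boolean
  "C": 1000.0
  "C_R": 100.0
  "C_S": 100.0
drug_effects:
  tmz:
    emax_r: 0.0959
    eta_r: 3.0
    ic50_r: 190.0
    emax_s: 0.0908
    eta_s: 3.0
    ic50_s: 23.33
  AC26:
    emax_r: 0.0999
    eta_r: 3.0
    ic50_r: 0.76
    emax_s: 0.0811
    eta_s: 3.0
    ic50_s: 0.9
  AC2:
    emax_r: 0.0986
    eta_r: 3.0
    ic50_r: 1.53
    emax_s: 0.0822
    eta_s: 3.0
    ic50_s: 1.53
  AC7:
    emax_r: 0.1062
    eta_r: 3.0
    ic50_r: 1.05
    emax_s: 0.0787
    eta_s: 3.0
    ic50_s: 5.67
horizons:
  dose_response_h: 72.0
  steady_state_max_h: 300.0
  steady_state_tol: 1.0e-6
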