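# Default cell on the two-state micropattern (all model keys at their
# defaults; shown here for reference and easy editing).
model:
  gamma: 0.8        # line tension, units of gamma0
  lambda: 4.8       # interface width, um
  kappa: 6000       # area-constraint strength
  R0: 18            # target radius, um
  eta: 0.67         # friction
  M: 0.75           # transport coefficient
  alpha: 1.4        # motility-force magnitude
  mu_beta: 7.5      # patch amplitude mean
  sigma_beta: 37.5  # patch amplitude s.d.
  sigma: 6.7        # patch width, um
  tau_f: 2.2        # patch period, seconds
  tau_chi: 9.6      # off-pattern inhibition, seconds
  tau_s: 8          # perimeter inhibition, minutes
  tau: 4            # polarity decay, minutes
  ell: 6            # filopodial probe distance, um
pattern:
  kind: two_state
ensemble:
  n_runs: 4800
  hours: 48
  seed: 1
inference:
  dt_sample: 10
  n_x: 36
  n_v: 30
  min_count: 20
  bootstrap: 0
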