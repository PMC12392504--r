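# Parameter-perturbation runs: uncomment one block at a time.
# Each is the default cell with a single change.

# --- smaller cell (bistable regime candidate) ---
model:
  R0: 15
pattern:
  kind: two_state
ensemble: {n_runs: 20, hours: 12, seed: 1}

# --- stiff cell ---
# model: {gamma: 1.8}

# --- stiff cell with slower patch delivery ---
# model: {gamma: 1.8, tau_f: 3.6}

# --- knockouts ---
# model: {no_filopodia: true}   # p(theta) ~ P(theta) only
# model: {tau_chi: .inf}        # no off-pattern polarity inhibition
# model: {s0: .inf}             # no perimeter inhibition
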