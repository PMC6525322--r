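# Calibrated canonical configuration of the plastic-attractor WM network.
# Fixed by calibrate(): the cell at which the invariant suite and the
# qualitative behavioral battery (persistence, winner uniqueness, capacity,
# serial position, retro-cueing, pulse effects) all express.
n_dims: 3
n_feat_per_dim: 4
n_conj: 4
tau: 5.0
beta_f: 1.4
beta_c: 1.0
eta: 0.02
w_init_scale: 0.02
w_norm: 1.0
noise_sigma: 0.22
gain: 6.0
threshold: 0.6
stim_drive: 1.0
readout_threshold: 0.5
variant: full
facil_U: 0.2
facil_tau: 150.0
report_dim: 2
probe_dim: 1
timing:
  reset: 10
  stim: 50
  gap: 10
  delay: 200
  cue: 30
  pulse: 10
  probe: 100
  readout: 50
  blank: 50
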