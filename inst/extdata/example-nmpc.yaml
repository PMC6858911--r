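# Example closed-loop run: near-threshold synthetic patient, two missed
# dose days and a mid-run bleed.
patient:
  seed: 2
  profile: near_threshold
nmpc:
  period: 1
  T_total: 56
  c_gamma: 0.1
  u_max: 1000
  target_hgb: 10.5
scenario:
  missed: [23, 24]
  bleeds:
    day: [35]
    target_hgb: [8.5]
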