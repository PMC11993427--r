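# Example protocol description for `cardioflow timing --protocol <file>`
flow:
  tr: 6.3          # ms
  k_seg: 2         # k-space segmentation factor
  n_encodes: 4     # velocity encodes per line (3-directional + reference)
asl:
  matrix_lines: 96
  tr: 3.2          # ms
  sense_factor: 1
  overhead: 133    # ms, fat saturation + flip-angle ramp
  rr_interval: 983.6
  inversion_fraction: 0.77
  n_pairs: 6
  breath_hold_s: 12
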