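# Panel layout for a 600-seedling greening panel.
# Units: blocks (rows/cols), pixels (block dims, origin), seconds
# (frame_times_s), hours (times_h, period_h).
grid:
  rows: 20
  cols: 30
  block_height_px: 71
  block_width_px: 72
  origin_row: 1
  origin_col: 1
frame_times_s: [0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26]
times_h: [4, 8, 12, 16, 20, 24]
period_h: 24
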