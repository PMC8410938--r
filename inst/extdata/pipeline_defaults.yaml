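# Default pipeline settings: every window and threshold of the analysis in
# one place. Frame ranges are 1-based inclusive at 100 Hz.
bin_factor: 4            # spatial binning (4 x 4 block average)
baseline_window: [31, 120]   # F0 window: 90 frames, 900 ms
r0_window: [31, 120]         # R0 window for dR/R
vessel_threshold: 500    # counts; binned donor pixels below are excluded
hb_band: [5, 14]         # Hz; heartbeat search band
movement_threshold_pct: 0.5  # changed-pixel separator, strict inequality
include_movement: false
map_scale_limits: [-0.5, 0.5]  # % dR/R colour clip
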