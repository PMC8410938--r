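# Shared fixtures: small, fast synthetic configurations built in code.

# Tiny raw frame (48 x 80 -> 12 x 20 binned) with the standard trial timing;
# fast enough for per-operation tests.
tiny_config <- function(...) {
  synthetic_config(raw_shape = c(48L, 80L), behavior_shape = c(40L, 64L), ...)
}

# Noiseless, vessel-free, equal-modulation tiny config with explicit unit
# ratio sensitivity; recovered dR/R equals the configured truth up to count
# quantisation.
clean_config <- function(heartbeat = list(donor_mod_depth = 0.02,
                                          acceptor_mod_depth = 0.02),
                         gain_coupling = list(g_D = 0.5, g_A = 0.5), ...) {
  tiny_config(optics = list(noise_sd_counts = 0),
              heartbeat = heartbeat, gain_coupling = gain_coupling,
              vessel_spec = list(), behavior_noise_sd = 0, ...)
}

# Difference-of-exponentials kernel written out directly: the independent
# oracle for generator kernels (unit peak, onset-delayed).
oracle_doe <- function(t, onset, rise_tau, decay_tau) {
  tt <- t - onset
  v <- ifelse(tt > 0, exp(-tt / decay_tau) - exp(-tt / rise_tau), 0)
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  v / (exp(-tpk / decay_tau) - exp(-tpk / rise_tau))
}

# Hand-built normalized sequence (norm_seq) from explicit donor/acceptor
# F/F0 stacks, bypassing the renderer; for exact-arithmetic tests.
manual_norm_seq <- function(donor_norm, acceptor_norm, frame_rate = 100,
                            dark_frames = c(1L, 2L), stim_frames = 60L,
                            baseline_window = c(5L, 40L)) {
  structure(list(
    donor_norm = donor_norm, acceptor_norm = acceptor_norm,
    baseline_window = as.integer(baseline_window),
    valid_mask = matrix(TRUE, dim(donor_norm)[1], dim(donor_norm)[2]),
    frame_rate = frame_rate, dark_frames = as.integer(dark_frames),
    stim_frames = as.integer(stim_frames), pixel_size = 14.55
  ), class = "norm_seq")
}

# Hand-built ratio sequence for metrics/maps tests.
manual_ratio_seq <- function(drr, frame_rate = 100, stim_frames = 125L,
                             r0_window = c(31L, 120L),
                             valid_mask = NULL, pixel_size = 14.55) {
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dim(drr)[1], dim(drr)[2])
  structure(list(drr = drr, r0_window = as.integer(r0_window),
                 valid_mask = valid_mask, frame_rate = frame_rate,
                 dark_frames = c(1L, 2L),
                 stim_frames = as.integer(stim_frames),
                 pixel_size = pixel_size, equalization = NULL),
            class = "ratio_seq")
}

# Single-region layout helpers.
square_layout <- function(side_mm = 1, bregma_px = c(150, 50),
                          pixel_size = 14.55, midline_angle = 0) {
  atlas_layout(regions = list(SQ = cbind(x = c(0, side_mm, side_mm, 0),
                                         y = c(0, 0, side_mm, side_mm))),
               bregma_px = bregma_px, midline_angle = midline_angle,
               pixel_size = pixel_size)
}
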