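#' Default region response kernels for a stimulus type
#'
#' Returns the per-region evoked-response kernel parameters the synthetic
#' generator uses for a given stimulus. Amplitudes and latencies for the
#' primary responding regions are the published means for this preparation
#' (forepaw: 0.195 %dR/R peaking 59.83 ms after the stimulus in S1FL, with a
#' smaller 0.112 % response in M1 at 61.96 ms; whisker: 0.156 % at 50.58 ms in
#' S1BF); secondary depolarisations and the slow cross-modal
#' hyperpolarisations are plausible values chosen once for the generator (see
#' the methods vignette).
#'
#' Each element is a list with fields `A_dep` (% dR/R), `onset_delay` (ms),
#' `peak_latency` (ms post-stimulus, used to solve the rise time constant),
#' `decay_tau` (ms), `A_hyp` (%, magnitude), `hyp_peak_time` (ms) and
#' `hyp_decay_tau` (ms).
#'
#' @param stimulus "paw", "whisker" or "none".
#' @return Named list of kernel parameter lists (names are region names).
#' @export
default_region_kernels <- function(stimulus = c("paw", "whisker", "none")) {
  stimulus <- match.arg(stimulus)
  k <- function(A_dep = 0, onset_delay = 10, peak_latency = 60, decay_tau = 90,
                A_hyp = 0, hyp_onset = 100, hyp_peak_time = 180,
                hyp_decay_tau = 250) {
    list(A_dep = A_dep, onset_delay = onset_delay, peak_latency = peak_latency,
         decay_tau = decay_tau, A_hyp = A_hyp, hyp_onset = hyp_onset,
         hyp_peak_time = hyp_peak_time, hyp_decay_tau = hyp_decay_tau)
  }
  switch(stimulus,
    paw = list(
      S1FL = k(A_dep = 0.195, peak_latency = 59.83, A_hyp = 0.03,
               hyp_peak_time = 180),
      M1   = k(A_dep = 0.112, peak_latency = 61.96, A_hyp = 0.02,
               hyp_peak_time = 180),
      M2   = k(A_dep = 0.08,  peak_latency = 65),
      S1HL = k(A_dep = 0.05,  peak_latency = 62),
      S1BF = k(A_dep = 0,     A_hyp = 0.05, hyp_onset = 60,
               hyp_peak_time = 120)
    ),
    whisker = list(
      S1BF = k(A_dep = 0.156, peak_latency = 50.58, A_hyp = 0.03,
               hyp_peak_time = 180),
      M2   = k(A_dep = 0.05,  peak_latency = 65),
      S1FL = k(A_dep = 0,     A_hyp = 0.04, hyp_onset = 60,
               hyp_peak_time = 120),
      S1HL = k(A_dep = 0,     A_hyp = 0.03, hyp_peak_time = 150),
      M1   = k(A_dep = 0,     A_hyp = 0.03, hyp_peak_time = 150)
    ),
    none = list()
  )
}

#' Synthetic acquisition configuration
#'
#' Builds the configuration for the forward model that emulates a dual-camera
#' FRET-GEVI acquisition: 200 frames at 100 Hz, camera dark frames 1-25,
#' excitation light on from frame 26, stimulus at frame 125 (1000 ms after
#' light-on), 12-bit cameras. The defaults are the acquisition conditions the
#' analysis defaults assume; the raw frame size defaults to a 240 x 384
#' reduced scale of the native 1200 x 1920 sensor with the physical field of
#' view preserved through the pixel size.
#'
#' @param frame_rate Acquisition rate, Hz.
#' @param n_frames Frames per trial.
#' @param raw_shape Integer c(rows, cols) of the raw frames; both divisible by
#'   `bin_factor`.
#' @param dark_frames 1-based inclusive range of camera-offset (dark) frames.
#' @param stim_frames 1-based stimulus frame indices (strictly increasing, all
#'   after the dark range).
#' @param stim_factors Per-stimulus amplitude scale factors (adaptation of the
#'   generated truth); recycled to length of `stim_frames`.
#' @param stimulus Stimulus type selecting the default region kernels.
#' @param region_kernels Named list of kernel parameter lists (see
#'   [default_region_kernels()]); overrides `stimulus` defaults if given.
#' @param latency_jitter_sd Across-trial SD (ms) of the depolarisation peak
#'   latency; 0 disables jitter.
#' @param heartbeat List: `f_hb` (Hz), `donor_mod_depth`, `acceptor_mod_depth`
#'   (fractional amplitude), `phase` (rad).
#' @param optics List: `donor_base_counts`, `acceptor_base_counts`,
#'   `camera_offset_counts`, `noise_sd_counts` (Gaussian, shot-like).
#' @param gain_coupling List with `g_D`, `g_A`: fractional dF/F per unit
#'   voltage (%), applied with opposite signs (donor decreases on
#'   depolarisation). The default derives g_D = g_A = 1 / (1 + m_A / m_D) so
#'   the equalised ratio has unit sensitivity: the configured truth is in %
#'   units of the final readout.
#' @param vessel_spec List of vessel segments, each
#'   `list(from = c(row_frac, col_frac), to = c(row_frac, col_frac),
#'   width_frac)` in fractions of the raw frame; rendered at offset level.
#' @param behavior_shape Integer c(rows, cols) of the behaviour camera frames.
#' @param behavior_noise_sd Behaviour-camera noise SD, counts.
#' @param bin_factor Spatial binning factor of the analysis.
#' @param pixel_size_um Physical size (um) of a *binned* pixel at native
#'   resolution scale; scaled automatically for reduced `raw_shape`.
#' @param seed Default seed used when none is passed to the generator ops.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(frame_rate = 100,
                             n_frames = 200,
                             raw_shape = c(240L, 384L),
                             dark_frames = c(1L, 25L),
                             stim_frames = 125L,
                             stim_factors = 1,
                             stimulus = c("paw", "whisker", "none"),
                             region_kernels = NULL,
                             latency_jitter_sd = 0,
                             heartbeat = list(),
                             optics = list(),
                             gain_coupling = NULL,
                             vessel_spec = default_vessel_spec(),
                             behavior_shape = c(120L, 192L),
                             behavior_noise_sd = 2,
                             bin_factor = 4L,
                             pixel_size_um = 14.55,
                             seed = 1L) {
  stimulus <- match.arg(stimulus)
  heartbeat <- modifyList(
    list(f_hb = 10, donor_mod_depth = 0.02, acceptor_mod_depth = 0.01,
         phase = 0.7),
    heartbeat)
  optics <- modifyList(
    list(donor_base_counts = 2000, acceptor_base_counts = 2000,
         camera_offset_counts = 100, noise_sd_counts = 10),
    optics)
  if (is.null(region_kernels)) region_kernels <- default_region_kernels(stimulus)
  if (is.null(gain_coupling)) {
    g <- 1 / (1 + heartbeat$acceptor_mod_depth / heartbeat$donor_mod_depth)
    gain_coupling <- list(g_D = g, g_A = g)
  }

  cfg <- structure(list(
    frame_rate = check_scalar_num(frame_rate, "frame_rate", lower = 1),
    n_frames = as.integer(check_scalar_num(n_frames, "n_frames", lower = 2)),
    raw_shape = as.integer(raw_shape),
    dark_frames = as.integer(dark_frames),
    stim_frames = as.integer(stim_frames),
    stim_factors = rep_len(as.numeric(stim_factors), length(stim_frames)),
    stimulus = stimulus,
    region_kernels = region_kernels,
    latency_jitter_sd = check_scalar_num(latency_jitter_sd,
                                         "latency_jitter_sd", lower = 0),
    heartbeat = heartbeat,
    optics = optics,
    gain_coupling = gain_coupling,
    vessel_spec = vessel_spec,
    behavior_shape = as.integer(behavior_shape),
    behavior_noise_sd = check_scalar_num(behavior_noise_sd,
                                         "behavior_noise_sd", lower = 0),
    bin_factor = as.integer(bin_factor),
    # native sensor is 1200 rows; reduced rasters keep the field of view
    pixel_size_um = pixel_size_um * (1200 / raw_shape[1]),
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  hb <- cfg$heartbeat
  op <- cfg$optics
  if (hb$f_hb <= 0 || hb$f_hb >= cfg$frame_rate / 2) {
    abort("heartbeat f_hb must lie strictly inside (0, frame_rate / 2)")
  }
  if (hb$donor_mod_depth < 0 || hb$acceptor_mod_depth < 0) {
    abort("heartbeat modulation depths must be >= 0")
  }
  if (op$donor_base_counts < 0 || op$acceptor_base_counts < 0 ||
      op$camera_offset_counts < 0 || op$noise_sd_counts < 0) {
    abort("optics counts and noise SD must be >= 0")
  }
  cfg$dark_frames <- check_frame_range(cfg$dark_frames, cfg$n_frames,
                                       "dark_frames")
  if (length(cfg$stim_frames) && any(diff(cfg$stim_frames) <= 0)) {
    abort("stim_frames must be strictly increasing")
  }
  if (length(cfg$stim_frames) &&
      cfg$dark_frames[2] >= min(cfg$stim_frames)) {
    abort("dark_frames must precede the first stimulus frame")
  }
  if (length(cfg$stim_frames) && max(cfg$stim_frames) > cfg$n_frames) {
    abort("stim_frames must lie within 1..n_frames")
  }
  if (any(cfg$raw_shape %% cfg$bin_factor != 0)) {
    abort("raw_shape must be divisible by bin_factor")
  }
  for (nm in names(cfg$region_kernels)) {
    kk <- cfg$region_kernels[[nm]]
    if (kk$decay_tau <= 0 || kk$hyp_decay_tau <= 0) {
      abort(sprintf("region %s: time constants must be > 0", nm))
    }
    if (kk$A_dep < 0 || kk$A_hyp < 0) {
      abort(sprintf("region %s: amplitudes must be >= 0", nm))
    }
    if (kk$A_hyp > 0 && kk$hyp_peak_time <= kk$onset_delay) {
      abort(sprintf("region %s: hyp_peak_time must exceed onset_delay", nm))
    }
    if (kk$A_hyp > 0 && (is.null(kk$hyp_onset) ||
                         kk$hyp_onset < kk$onset_delay ||
                         kk$hyp_peak_time <= kk$hyp_onset)) {
      abort(sprintf(
        "region %s: need onset_delay <= hyp_onset < hyp_peak_time", nm))
    }
    if (kk$A_dep > 0 && kk$peak_latency <= kk$onset_delay) {
      abort(sprintf("region %s: peak_latency must exceed onset_delay", nm))
    }
    if (kk$A_dep > 0 && kk$peak_latency - kk$onset_delay >= kk$decay_tau) {
      abort(sprintf(
        "region %s: peak_latency - onset_delay must be < decay_tau", nm))
    }
    if (kk$A_hyp > 0 &&
        kk$hyp_peak_time - kk$hyp_onset >= kk$hyp_decay_tau) {
      abort(sprintf(
        "region %s: hyp_peak_time - hyp_onset must be < hyp_decay_tau", nm))
    }
  }
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d frames @ %g Hz, raw %d x %d px (binned pixel %.2f um)\n",
              x$n_frames, x$frame_rate, x$raw_shape[1], x$raw_shape[2],
              x$pixel_size_um))
  cat(sprintf("  dark frames %d-%d; stimulus '%s' at frame(s) %s\n",
              x$dark_frames[1], x$dark_frames[2], x$stimulus,
              paste(x$stim_frames, collapse = ", ")))
  cat(sprintf("  heartbeat %g Hz (mod depths D %.3f / A %.3f); noise sd %g counts\n",
              x$heartbeat$f_hb, x$heartbeat$donor_mod_depth,
              x$heartbeat$acceptor_mod_depth, x$optics$noise_sd_counts))
  invisible(x)
}

#' Default dark blood-vessel layout
#'
#' Three vessel segments in fractional raw-frame coordinates, rendered at
#' camera-offset level by the generator.
#' @return List of segment specs.
#' @export
default_vessel_spec <- function() {
  list(
    list(from = c(0.05, 0.30), to = c(0.95, 0.38), width_frac = 0.020),
    list(from = c(0.10, 0.70), to = c(0.90, 0.62), width_frac = 0.015),
    list(from = c(0.50, 0.05), to = c(0.58, 0.95), width_frac = 0.012)
  )
}

# Rise time constant of a difference-of-exponentials kernel
# a(t) = exp(-t/decay_tau) - exp(-t/rise_tau), solved so the kernel peaks at
# `peak_offset` ms after onset. Peak time is ln(d/r) * r * d / (d - r), which
# increases monotonically from 0 (r -> 0) to d (r -> d).
solve_rise_tau <- function(peak_offset, decay_tau) {
  stopifnot(peak_offset > 0, peak_offset < decay_tau)
  f <- function(r) log(decay_tau / r) * r * decay_tau / (decay_tau - r) -
    peak_offset
  uniroot(f, lower = 1e-6, upper = decay_tau - 1e-6, tol = 1e-10)$root
}

# Normalised difference-of-exponentials kernel: zero before `onset`, unit peak
# at onset + peak_offset (continuous time).
doe_kernel <- function(t, onset, rise_tau, decay_tau) {
  tt <- t - onset
  v <- ifelse(tt > 0, exp(-tt / decay_tau) - exp(-tt / rise_tau), 0)
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  v / peak
}
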