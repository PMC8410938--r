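# Forward rendering: truth -> dual-channel counts and behaviour stacks.

#' Render a dual-channel trial from ground truth
#'
#' Per-channel signal model, per pixel x and frame t (lit frames):
#' `D(x,t) = offset + F_D * (1 - g_D * V(x,t) / 100) * (1 + m_D * sin(2 pi f_hb t + phi)) + noise`
#' and analogously for the acceptor with `+g_A` and `m_A` — the donor dims
#' and the acceptor brightens with depolarisation, both riding on a
#' common-frequency heartbeat oscillation with channel-specific modulation
#' depth. Dark frames (camera offset only) and vessel pixels carry no
#' fluorescence. Counts are rounded and clipped to the 12-bit range after
#' noise.
#'
#' @param truth A [generate_voltage_truth()] result.
#' @param config The same [synthetic_config()] (defaults to the one stored in
#'   `truth`).
#' @param seed Integer seed for the photon-noise draw.
#' @return A [dual_channel_seq()] of integer-valued counts at raw resolution.
#' @export
render_trial <- function(truth, config = truth$config, seed = config$seed) {
  stopifnot(inherits(truth, "voltage_truth"))
  h <- config$raw_shape[1]; w <- config$raw_shape[2]
  nt <- config$n_frames
  dark <- config$dark_frames[1]:config$dark_frames[2]
  lit <- setdiff(seq_len(nt), dark)
  hb <- config$heartbeat; op <- config$optics; gc <- config$gain_coupling

  # every pixel renders one of a small set of time courses ("levels"):
  # level 1 = vessel (offset only), level 2 = unlabeled tissue (V = 0),
  # level 2+k = atlas region k (kernel matched by name; V = 0 if none)
  atlas_regions <- attr(truth$label_binned, "regions")
  nlev <- length(atlas_regions) + 2L
  Vlev <- matrix(0, nlev, nt)
  hit <- match(atlas_regions, rownames(truth$V))
  for (k in seq_along(atlas_regions)) {
    if (!is.na(hit[k])) Vlev[k + 2L, ] <- truth$V[hit[k], ]
  }
  # 0-based level index per pixel: 0 = vessel, 1 = unlabeled, 1+k = region k
  level <- as.vector(truth$label_raw) + 1L
  level[as.vector(truth$vessel_mask)] <- 0L

  t_abs <- (lit - 1) / config$frame_rate
  hb_sin <- sin(2 * pi * hb$f_hb * t_abs + hb$phase)

  channel <- function(base, g, sign, mod, chan_seed) {
    lut <- matrix(op$camera_offset_counts, nlev, nt)
    fluo <- 1 + sign * g * Vlev[-1, lit, drop = FALSE] / 100
    fluo <- fluo * rep(1 + mod * hb_sin, each = nlev - 1L)
    lut[-1, lit] <- op$camera_offset_counts + base * fluo
    counts <- render_counts_cpp(lut, level, op$noise_sd_counts, 4095,
                                chan_seed)
    dim(counts) <- c(h, w, nt)
    counts
  }
  donor <- channel(op$donor_base_counts, gc$g_D, -1, hb$donor_mod_depth,
                   derive_seed(seed, 11))
  acceptor <- channel(op$acceptor_base_counts, gc$g_A, +1,
                      hb$acceptor_mod_depth, derive_seed(seed, 12))
  dual_channel_seq(donor, acceptor,
                   frame_rate = config$frame_rate,
                   dark_frames = config$dark_frames,
                   stim_frames = config$stim_frames,
                   pixel_size = config$pixel_size_um / config$bin_factor)
}

#' Generate a behaviour-camera stack with optional movement epochs
#'
#' A static textured scene (the head-fixed mouse silhouette) plus camera
#' noise; during each movement epoch a rectangular sub-region covering
#' `area_frac` of the frame is translated by `shift_px` pixels, so
#' frame-to-frame differences outside epochs are pure noise while epoch
#' frames change a known fraction of pixels.
#'
#' @param config A [synthetic_config()] (uses `behavior_shape`,
#'   `behavior_noise_sd`, `n_frames`).
#' @param movement_epochs List of 1-based inclusive frame ranges
#'   (`c(first, last)`).
#' @param seed Integer seed.
#' @param area_frac Fraction of frame area displaced during epochs (in (0, 1]).
#' @param shift_px Translation in pixels (>= 2 to defeat noise thresholds).
#' @return Numeric 3-d array [rows, cols, frames] of counts, with attributes
#'   `movement_epochs` and `moving_frac`.
#' @export
generate_behavior_stack <- function(config, movement_epochs = list(),
                                    seed = config$seed, area_frac = 0.05,
                                    shift_px = 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (area_frac > 1 || area_frac <= 0) {
    abort("area_frac must lie in (0, 1]")
  }
  for (ep in movement_epochs) {
    if (ep[1] < 1 || ep[2] > config$n_frames || ep[1] > ep[2]) {
      abort("movement epochs must be 1-based ranges within 1..n_frames")
    }
  }
  set.seed(seed)
  h <- config$behavior_shape[1]; w <- config$behavior_shape[2]
  nt <- config$n_frames
  # static texture: smooth background plus speckle, mid-range 12-bit counts
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # integer-valued texture: with sub-count texture offsets, count rounding
  # would give pixels near half-integers systematically wider frame-to-frame
  # differences than the noise calibration assumes
  base <- round(1200 + 600 * sin(2 * pi * rr / h) * cos(2 * pi * cc / w) +
                  matrix(runif(h * w, 0, 800), h, w))
  # displaced rectangle centred in the frame, area = area_frac of pixels
  rh <- max(2L, round(sqrt(area_frac * h * w * h / w)))
  rw <- max(2L, ceiling(area_frac * h * w / rh))
  r0 <- max(1L, (h - rh) %/% 2L); c0 <- max(1L, (w - rw) %/% 2L)
  moved <- base
  src_r <- r0 + seq_len(rh) - 1L
  src_c <- c0 + seq_len(rw) - 1L
  dst_c <- pmin(src_c + as.integer(shift_px), w)
  moved[src_r, src_c] <- min(base)   # vacated area goes dark
  moved[src_r, dst_c] <- base[src_r, src_c]
  in_epoch <- rep(FALSE, nt)
  for (ep in movement_epochs) in_epoch[ep[1]:ep[2]] <- TRUE
  stack <- array(rep(base, nt), c(h, w, nt))
  if (any(in_epoch)) stack[, , in_epoch] <- rep(moved, sum(in_epoch))
  stack <- noise_clip_cpp(stack, config$behavior_noise_sd, 4095,
                          derive_seed(seed, 21))
  dim(stack) <- c(h, w, nt)
  attr(stack, "movement_epochs") <- movement_epochs
  attr(stack, "moving_frac") <- mean(moved != base)
  stack
}

#' Simulate one complete trial in memory
#'
#' Convenience wrapper: ground truth, rendered dual-channel sequence and
#' behaviour stack for a single trial, without touching the filesystem.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; sub-seeds for truth, rendering and behaviour are
#'   derived from it deterministically.
#' @param movement_epochs Movement epochs for the behaviour stack.
#' @param behavior Also render the behaviour stack (skip for imaging-only
#'   experiments).
#' @return List with `truth`, `seq`, `behavior` (`NULL` when skipped).
#' @export
simulate_trial <- function(config, seed = config$seed,
                           movement_epochs = list(), behavior = TRUE) {
  truth <- generate_voltage_truth(config, seed = derive_seed(seed, 1))
  truth$movement_epochs <- movement_epochs
  seq <- render_trial(truth, config, seed = derive_seed(seed, 2))
  beh <- if (behavior) {
    generate_behavior_stack(config, movement_epochs,
                            seed = derive_seed(seed, 3))
  }
  list(truth = truth, seq = seq, behavior = beh)
}
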