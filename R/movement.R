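# Movement-based trial selection from the behaviour camera.
#
# A stationary reference recording (a fabric mouse in the head holder)
# calibrates the per-pixel noise level; a live trial's pixels count as
# "changed" when their absolute difference from the stimulation frame exceeds
# that calibrated change, and a trial is labelled "movement" when the changed
# fraction of any analysed frame exceeds 0.5 % (strict inequality — the
# threshold is a separating value).

#' Calibrate per-pixel noise thresholds from a stationary reference stack
#'
#' The per-pixel threshold is the largest absolute intensity difference seen
#' between frames of the stationary recording (`statistic = "max"`: the
#' per-pixel range, i.e. the maximum over all frame pairs), so the stationary
#' stack itself always yields 0 % changed pixels — including against its
#' designated stimulation-time frame, whichever frame that is. A percentile
#' statistic (of the differences to the reference frame) is available for
#' long recordings with rare outliers.
#'
#' @param stationary_stack 3-d array [rows, cols, frames] of behaviour-camera
#'   counts with no real movement.
#' @param ref_frame Frame index playing the role of the stimulation frame;
#'   default the middle frame.
#' @param statistic "max" or "percentile".
#' @param prob Percentile (used when `statistic = "percentile"`).
#' @param min_frames Minimum frames required.
#' @return Object of class `noise_calibration`: `threshold` matrix (counts),
#'   `ref_frame`, `statistic`, summary stats.
#' @export
calibrate_noise <- function(stationary_stack, ref_frame = NULL,
                            statistic = c("max", "percentile"), prob = 0.99,
                            min_frames = 30L) {
  check_stack(stationary_stack, "stationary_stack")
  statistic <- match.arg(statistic)
  nt <- dim(stationary_stack)[3]
  if (nt < min_frames) {
    abort(sprintf("stationary stack has %d frames; at least %d required",
                  nt, min_frames))
  }
  if (is.null(ref_frame)) ref_frame <- as.integer(ceiling(nt / 2))
  thr <- if (statistic == "max") {
    # per-pixel range = max absolute difference over all frame pairs
    apply(stationary_stack, c(1, 2), max) -
      apply(stationary_stack, c(1, 2), min)
  } else {
    ref <- stationary_stack[, , ref_frame]
    diffs <- abs(stationary_stack - as.vector(ref))
    apply(diffs, c(1, 2), stats::quantile, probs = prob, names = FALSE)
  }
  structure(list(threshold = thr, ref_frame = ref_frame,
                 statistic = statistic, prob = prob,
                 summary = c(mean = mean(thr), max = max(thr),
                             median = stats::median(thr))),
            class = "noise_calibration")
}

#' Per-frame changed-pixel fractions around the stimulus
#'
#' For each frame in the analysis window (10 frames before the stimulus to 60
#' frames after), the percentage of pixels whose absolute difference from the
#' stimulation frame exceeds the calibrated per-pixel threshold. The
#' stimulation frame itself scores 0 by definition.
#'
#' @param behavior_stack 3-d array of behaviour-camera counts.
#' @param stim_frame 1-based stimulation frame.
#' @param calib A [calibrate_noise()] result (shape must match the frames).
#' @param pre_frames,post_frames Analysis window extent in frames.
#' @return Tibble: `frame`, `offset_frames` (relative to stimulus),
#'   `changed_pct`. If the stack truncates the window, only the covered
#'   sub-window is returned (recorded in the `window` attribute).
#' @export
changed_pixel_fraction <- function(behavior_stack, stim_frame, calib,
                                   pre_frames = 10L, post_frames = 60L) {
  check_stack(behavior_stack, "behavior_stack")
  stopifnot(inherits(calib, "noise_calibration"))
  d <- dim(behavior_stack)
  if (!identical(d[1:2], dim(calib$threshold))) {
    abort("behavior stack and calibration shapes differ")
  }
  want <- (stim_frame - pre_frames):(stim_frame + post_frames)
  frames <- want[want >= 1L & want <= d[3]]
  if (!length(frames)) abort("analysis window lies outside the stack")
  ref <- as.vector(behavior_stack[, , stim_frame])
  thr <- as.vector(calib$threshold)
  m <- matrix(behavior_stack[, , frames], ncol = length(frames))
  changed <- colMeans(abs(m - ref) > thr) * 100
  out <- tibble::tibble(frame = frames,
                        offset_frames = frames - stim_frame,
                        changed_pct = changed)
  attr(out, "window") <- range(frames)
  attr(out, "truncated") <- !identical(frames, want)
  out
}

#' Classify a trial as quiet or movement
#'
#' The trial is labelled "movement" when any analysed frame's changed-pixel
#' fraction strictly exceeds the threshold (default 0.5 %, the empirical
#' separator between visible movement and quiet breathing). A guard flag
#' additionally marks whether an exceedance falls within `guard_window_ms` of
#' the stimulus, where movement-contaminated optical signals are most
#' damaging.
#'
#' @param fractions Tibble from [changed_pixel_fraction()].
#' @param threshold_pct Changed-pixel threshold in percent.
#' @param guard_window_ms Half-width (ms) of the peri-stimulus guard window.
#' @param frame_rate Hz.
#' @return One-row tibble: `label` ("quiet"/"movement"), `max_changed_pct`,
#'   `movement_near_stim` (guard flag), `n_frames_over`.
#' @export
classify_trial <- function(fractions, threshold_pct = 0.5,
                           guard_window_ms = 100, frame_rate = 100) {
  over <- fractions$changed_pct > threshold_pct
  dt <- frame_dt_ms(frame_rate)
  near <- abs(fractions$offset_frames * dt) <= guard_window_ms
  tibble::tibble(
    label = if (any(over)) "movement" else "quiet",
    max_changed_pct = max(fractions$changed_pct),
    movement_near_stim = any(over & near),
    n_frames_over = sum(over)
  )
}

#' One-call movement classification of a behaviour stack
#'
#' @inheritParams changed_pixel_fraction
#' @inheritParams classify_trial
#' @return One-row tibble from [classify_trial()].
#' @export
classify_movement <- function(behavior_stack, stim_frame, calib,
                              threshold_pct = 0.5, guard_window_ms = 100,
                              frame_rate = 100) {
  fr <- changed_pixel_fraction(behavior_stack, stim_frame, calib)
  classify_trial(fr, threshold_pct, guard_window_ms, frame_rate)
}
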