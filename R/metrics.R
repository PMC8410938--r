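# Evoked-response quantification: peak depolarisation, inclusion rule,
# hyperpolarisation, timing, paired-pulse adaptation, cylinder-test AI.
#
# Conventions:
#   * baseline for single-stimulus metrics = mean of the 10 frames
#     immediately preceding the stimulus frame (100 ms at 100 Hz);
#   * peak window = 20-100 ms post-stimulus, endpoints inclusive
#     (frames stim+2 .. stim+10 at 100 Hz); ties break to the earliest frame;
#   * inclusion: peak_amp >= 2 * baseline SD (boundary inclusive — the
#     exclusion rule is "less than two times the SD");
#   * hyperpolarisation amplitude is reported as a positive magnitude of the
#     below-baseline excursion (0 if the trace never dips below baseline).

trace_vectors <- function(trace) {
  if (is.data.frame(trace)) {
    list(drr = trace$drr_pct, frames = trace$frame)
  } else {
    list(drr = as.numeric(trace), frames = seq_along(trace))
  }
}

#' Detect the evoked depolarisation peak of a region trace
#'
#' @param trace A region trace: either the tibble from [region_trace()] or a
#'   plain numeric vector of %dR/R per frame.
#' @param stim_frame 1-based stimulus frame index.
#' @param frame_rate Hz (default 100).
#' @param peak_window Post-stimulus search window in ms, inclusive.
#' @param baseline_frames Number of frames immediately preceding the stimulus
#'   used for the baseline mean and SD.
#' @return One-row tibble: `baseline_mean`, `baseline_sd`, `peak_amp` (%,
#'   relative to baseline), `peak_time_ms` (post-stimulus), `peak_frame`,
#'   `included` (2-SD rule).
#' @export
detect_peak <- function(trace, stim_frame, frame_rate = 100,
                        peak_window = c(20, 100), baseline_frames = 10L) {
  tv <- trace_vectors(trace)
  y <- tv$drr
  n <- length(y)
  bidx <- (stim_frame - baseline_frames):(stim_frame - 1L)
  widx <- frames_in_window_ms(stim_frame, peak_window[1], peak_window[2],
                              frame_rate, n)
  last_needed <- stim_frame +
    ceiling(peak_window[2] / frame_dt_ms(frame_rate) - 1e-9)
  if (min(bidx) < 1 || !length(widx) || last_needed > n) {
    abort("trace does not cover the baseline and peak windows")
  }
  b <- y[bidx]
  baseline_mean <- mean(b)
  baseline_sd <- stats::sd(b)
  rel <- y[widx] - baseline_mean
  k <- which.max(rel)  # earliest frame on ties
  peak_amp <- rel[k]
  tibble::tibble(
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    peak_amp = peak_amp,
    peak_time_ms = frame_time_ms(widx[k], stim_frame, frame_rate),
    peak_frame = widx[k],
    included = trial_inclusion(peak_amp, baseline_sd)
  )
}

#' Two-SD trial inclusion rule
#'
#' Trials whose maximum stimulation response amplitude is less than two times
#' the baseline standard deviation are excluded; the boundary (exactly 2 SD)
#' is included.
#'
#' @param peak_amp Peak amplitude relative to baseline, %.
#' @param baseline_sd Baseline SD, %.
#' @return Logical. The degenerate all-zero case (sd = 0, amp <= 0) is
#'   excluded.
#' @export
trial_inclusion <- function(peak_amp, baseline_sd) {
  if (any(baseline_sd < 0, na.rm = TRUE)) abort("baseline_sd must be >= 0")
  ifelse(baseline_sd == 0 & peak_amp <= 0, FALSE,
         peak_amp >= 2 * baseline_sd)
}

#' Measure the post-peak hyperpolarisation
#'
#' Minimum of (trace - baseline) from just after the depolarisation peak to
#' 300 ms after the stimulus; reported as a positive magnitude (0 when the
#' trace never dips below baseline), with the time of the minimum (earliest
#' frame on ties).
#'
#' @inheritParams detect_peak
#' @param peak_time_ms Time of the depolarisation peak, ms post-stimulus.
#' @param window_end_ms End of the search window, ms post-stimulus.
#' @return One-row tibble: `hyp_amp` (%, magnitude), `hyp_time_ms`,
#'   `hyp_value` (signed excursion).
#' @export
measure_hyperpolarisation <- function(trace, stim_frame, peak_time_ms,
                                      frame_rate = 100, window_end_ms = 300,
                                      baseline_frames = 10L) {
  tv <- trace_vectors(trace)
  y <- tv$drr
  n <- length(y)
  dt <- frame_dt_ms(frame_rate)
  bidx <- (stim_frame - baseline_frames):(stim_frame - 1L)
  widx <- frames_in_window_ms(stim_frame, peak_time_ms + dt, window_end_ms,
                              frame_rate, n)
  if (!length(widx)) abort("empty hyperpolarisation window")
  if (max(widx) > n) abort("trace does not cover the hyperpolarisation window")
  baseline_mean <- mean(y[bidx])
  rel <- y[widx] - baseline_mean
  k <- which.min(rel)
  tibble::tibble(
    hyp_amp = max(0, -rel[k]),
    hyp_time_ms = frame_time_ms(widx[k], stim_frame, frame_rate),
    hyp_value = rel[k]
  )
}

#' Time for the response to decay to half its peak
#'
#' First time after the peak at which the baseline-subtracted trace falls to
#' half the peak amplitude, with linear interpolation between the bracketing
#' frames (set `interpolate = FALSE` for strict frame resolution). `NA` if
#' the trace never reaches half-decay within its extent.
#'
#' @inheritParams detect_peak
#' @param peak A one-row tibble from [detect_peak()] (or a list with
#'   `peak_frame`, `peak_amp`, `baseline_mean`).
#' @param interpolate Linear sub-frame interpolation (default TRUE).
#' @return Half-decay time in ms post-stimulus, or `NA_real_`.
#' @export
decay50 <- function(trace, stim_frame, peak, frame_rate = 100,
                    interpolate = TRUE) {
  tv <- trace_vectors(trace)
  y <- tv$drr - peak$baseline_mean
  n <- length(y)
  half <- 0.5 * peak$peak_amp
  dt <- frame_dt_ms(frame_rate)
  f <- peak$peak_frame
  if (f >= n) return(NA_real_)
  for (i in (f + 1L):n) {
    if (!is.na(y[i]) && y[i] <= half) {
      t_i <- frame_time_ms(i, stim_frame, frame_rate)
      if (!interpolate) return(t_i)
      y0 <- y[i - 1L]; y1 <- y[i]
      if (is.na(y0) || y0 <= half || y0 == y1) return(t_i)
      frac <- (y0 - half) / (y0 - y1)
      return(t_i - dt + frac * dt)
    }
  }
  NA_real_
}

#' Full single-stimulus response metrics for one trace
#'
#' Combines [detect_peak()], [measure_hyperpolarisation()] and [decay50()]
#' into the per-trial, per-region metrics row.
#'
#' @inheritParams detect_peak
#' @param region,trial_id Identifier columns copied into the output.
#' @return One-row tibble of response metrics.
#' @export
response_metrics <- function(trace, stim_frame, frame_rate = 100,
                             region = NA_character_, trial_id = NA_character_) {
  pk <- detect_peak(trace, stim_frame, frame_rate)
  hy <- measure_hyperpolarisation(trace, stim_frame, pk$peak_time_ms,
                                  frame_rate)
  d50 <- decay50(trace, stim_frame, pk, frame_rate)
  tibble::tibble(trial_id = trial_id, region = region,
                 baseline_mean = pk$baseline_mean,
                 baseline_sd = pk$baseline_sd,
                 peak_amp = pk$peak_amp, peak_time_ms = pk$peak_time_ms,
                 included = pk$included,
                 hyp_amp = hy$hyp_amp, hyp_time_ms = hy$hyp_time_ms,
                 decay50_ms = d50)
}

#' Paired-pulse adaptation ratio
#'
#' Measures the depolarising peak evoked by each of two stimuli relative to
#' the signal immediately preceding that stimulus (mean of
#' `pre_frames` frames, default 2 = 20 ms), each in its own 20-100 ms
#' post-stimulus window, and returns the peak depolarisation ratio
#' amp2 / amp1 (undefined when amp1 <= 0). A ratio below 1 signals sensory
#' adaptation.
#'
#' @inheritParams detect_peak
#' @param stim_frames The two stimulus frames `c(s1, s2)`.
#' @param pre_frames Frames averaged for each stimulus' immediately-preceding
#'   baseline (configurable down to 1).
#' @param region,trial_id Identifier columns.
#' @return One-row tibble: `interstim_ms`, `amp1`, `amp2`, `ratio`.
#' @export
paired_pulse <- function(trace, stim_frames, frame_rate = 100,
                         peak_window = c(20, 100), pre_frames = 2L,
                         region = NA_character_, trial_id = NA_character_) {
  if (length(stim_frames) != 2L || diff(stim_frames) < 2L) {
    abort("stim_frames must be two frames at least 2 frames apart")
  }
  tv <- trace_vectors(trace)
  y <- tv$drr
  n <- length(y)
  amp_one <- function(s) {
    bidx <- (s - pre_frames):(s - 1L)
    widx <- frames_in_window_ms(s, peak_window[1], peak_window[2],
                                frame_rate, n)
    if (min(bidx) < 1 || !length(widx)) {
      abort("trace does not cover a stimulus' baseline/peak window")
    }
    max(y[widx]) - mean(y[bidx])
  }
  amp1 <- amp_one(stim_frames[1])
  amp2 <- amp_one(stim_frames[2])
  ratio <- if (amp1 > 0) amp2 / amp1 else NA_real_
  if (is.na(ratio)) warn("amp1 <= 0: adaptation ratio undefined")
  tibble::tibble(
    trial_id = trial_id, region = region,
    interstim_ms = diff(stim_frames) * frame_dt_ms(frame_rate),
    amp1 = amp1, amp2 = amp2, ratio = ratio
  )
}

#' Cylinder-test forelimb asymmetry index
#'
#' AI = (right - both/2) / (right + left + both) in the printed formula
#' (`variant = "minus"`); the `"plus"` variant uses (right + both/2) and
#' yields the symmetric value 0.5 for any number of both-forelimb contacts.
#' Symmetric forelimb use with no both-contacts gives 0.5 under either
#' variant.
#'
#' @param right,left,both Non-negative wall-contact counts.
#' @param variant "minus" (as printed) or "plus".
#' @return AI, dimensionless.
#' @export
asymmetry_index <- function(right, left, both = 0,
                            variant = c("minus", "plus")) {
  variant <- match.arg(variant)
  if (any(c(right, left, both) < 0)) abort("counts must be >= 0")
  denom <- right + left + both
  if (any(denom == 0)) abort("right + left + both must be > 0")
  num <- if (variant == "minus") right - both / 2 else right + both / 2
  num / denom
}
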