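# Shared helpers: frame/time conventions and argument checks.
#
# All frame indices in configs and user-facing arguments are 1-based inclusive
# (the acquisition convention: dark frames 1-25, baseline frames 31-120,
# stimulus frame 125). Time relative to a stimulus frame s is (f - s) * dt ms
# with dt = 1000 / frame_rate, so the stimulus frame itself is 0 ms.

frame_dt_ms <- function(frame_rate) 1000 / frame_rate

frame_time_ms <- function(frames, stim_frame, frame_rate) {
  (frames - stim_frame) * frame_dt_ms(frame_rate)
}

check_frame_range <- function(range, n_frames, what = "frame range") {
  if (length(range) != 2L || any(!is.finite(range))) {
    abort(sprintf("%s must be a length-2 numeric (first, last)", what))
  }
  range <- as.integer(range)
  if (range[1] < 1L || range[2] > n_frames || range[1] > range[2]) {
    abort(sprintf("%s [%d, %d] is not a valid 1-based range within 1..%d",
                  what, range[1], range[2], n_frames))
  }
  range
}

check_stack <- function(x, what = "stack") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort(sprintf("%s must be a 3-d array [rows, cols, frames]", what))
  }
  invisible(x)
}

check_scalar_num <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("%s must be a single finite number in [%s, %s]",
                  what, format(lower), format(upper)))
  }
  as.numeric(x)
}

# Derive a reproducible child seed (kept well below .Machine$integer.max).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

frames_in_window_ms <- function(stim_frame, from_ms, to_ms, frame_rate,
                                n_frames) {
  dt <- frame_dt_ms(frame_rate)
  f <- seq_len(n_frames)
  t <- (f - stim_frame) * dt
  f[t >= from_ms - 1e-9 & t <= to_ms + 1e-9]
}
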