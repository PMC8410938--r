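# Preprocessing: raw dual-channel stacks -> per-pixel %dR/R sequences.

#' Dual-channel (donor/acceptor) image sequence
#'
#' The raw input of the pipeline: simultaneously acquired donor and acceptor
#' frame stacks with timing metadata.
#'
#' @param donor,acceptor Numeric 3-d arrays [rows, cols, frames], camera
#'   counts; identical dimensions.
#' @param frame_rate Hz.
#' @param dark_frames 1-based inclusive range of camera dark frames.
#' @param stim_frames 1-based stimulus frame indices.
#' @param hemisphere_mask Logical matrix of pixels inside the imaged
#'   hemisphere; default all `TRUE`.
#' @param pixel_size um per pixel of the stacks as given.
#' @return Object of class `dual_channel_seq`.
#' @export
dual_channel_seq <- function(donor, acceptor, frame_rate = 100,
                             dark_frames = c(1L, 25L), stim_frames = 125L,
                             hemisphere_mask = NULL, pixel_size = 14.55) {
  check_stack(donor, "donor"); check_stack(acceptor, "acceptor")
  if (!identical(dim(donor), dim(acceptor))) {
    abort("donor and acceptor stacks must have identical dimensions")
  }
  nt <- dim(donor)[3]
  dark_frames <- check_frame_range(dark_frames, nt, "dark_frames")
  stim_frames <- as.integer(stim_frames)
  if (length(stim_frames) && dark_frames[2] >= min(stim_frames)) {
    abort("dark_frames must end before the first stimulus frame")
  }
  if (is.null(hemisphere_mask)) {
    hemisphere_mask <- matrix(TRUE, dim(donor)[1], dim(donor)[2])
  }
  structure(list(donor = donor, acceptor = acceptor,
                 frame_rate = as.numeric(frame_rate),
                 dark_frames = dark_frames, stim_frames = stim_frames,
                 hemisphere_mask = hemisphere_mask,
                 pixel_size = as.numeric(pixel_size)),
            class = "dual_channel_seq")
}

#' @export
print.dual_channel_seq <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf(
    "<dual_channel_seq> %d x %d px, %d frames @ %g Hz; dark %d-%d; stim %s\n",
    d[1], d[2], d[3], x$frame_rate, x$dark_frames[1], x$dark_frames[2],
    paste(x$stim_frames, collapse = ",")))
  invisible(x)
}

#' Spatially bin a frame stack by block averaging
#'
#' Each output pixel is the arithmetic mean of a `factor` x `factor` block, so
#' the global mean is preserved exactly (1920 x 1200 acquisition frames binned
#' by 4 give 480 x 300 images).
#'
#' @param stack 3-d array [rows, cols, frames] (a matrix is treated as one
#'   frame).
#' @param factor Integer binning factor; rows and cols must be divisible by
#'   it (no silent cropping).
#' @return Binned array.
#' @export
bin_spatial <- function(stack, factor = 4L) {
  factor <- as.integer(factor)
  one_frame <- is.matrix(stack)
  if (one_frame) stack <- array(stack, c(dim(stack), 1L))
  check_stack(stack)
  d <- dim(stack)
  if (d[1] %% factor != 0 || d[2] %% factor != 0) {
    abort(sprintf(
      paste0("stack of %d x %d is not divisible by factor %d; ",
             "crop to %d x %d first"),
      d[1], d[2], factor, (d[1] %/% factor) * factor,
      (d[2] %/% factor) * factor))
  }
  if (!is.double(stack)) storage.mode(stack) <- "double"
  out <- bin_stack_cpp(stack, d[1], d[2], d[3], factor)
  if (one_frame) out[, , 1] else out
}

#' Bin both channels (and masks) of a dual-channel sequence
#'
#' @param seq A [dual_channel_seq()].
#' @param factor Binning factor.
#' @return A new `dual_channel_seq` with binned stacks, a binned hemisphere
#'   mask (a binned pixel is inside if the majority of its block is) and the
#'   pixel size scaled by `factor`.
#' @export
bin_sequence <- function(seq, factor = 4L) {
  stopifnot(inherits(seq, "dual_channel_seq"))
  hm <- bin_spatial(seq$hemisphere_mask * 1, factor) >= 0.5
  dual_channel_seq(bin_spatial(seq$donor, factor),
                   bin_spatial(seq$acceptor, factor),
                   frame_rate = seq$frame_rate,
                   dark_frames = seq$dark_frames,
                   stim_frames = seq$stim_frames,
                   hemisphere_mask = hm,
                   pixel_size = seq$pixel_size * factor)
}

#' Subtract the camera dark offset
#'
#' The per-pixel, per-channel offset is the mean over the dark frames
#' (acquired before the excitation light turns on) and is subtracted from
#' every frame, leaving the dark frames themselves zero-mean.
#'
#' @param seq A [dual_channel_seq()].
#' @return `dual_channel_seq` with offset-subtracted stacks.
#' @export
subtract_dark_offset <- function(seq) {
  stopifnot(inherits(seq, "dual_channel_seq"))
  dk <- seq$dark_frames[1]:seq$dark_frames[2]
  sub1 <- function(x) {
    off <- rowMeans(x[, , dk, drop = FALSE], dims = 2)
    x - as.vector(off)  # recycles over frames (column-major)
  }
  seq$donor <- sub1(seq$donor)
  seq$acceptor <- sub1(seq$acceptor)
  seq
}

#' Normalise each pixel by its pre-stimulus average
#'
#' Divides every pixel trace by its mean over the pre-stimulus baseline
#' window, per channel, yielding dimensionless F/F0 stacks whose baseline
#' mean is exactly 1. Pixels with non-positive F0 (vessel-like) are flagged
#' invalid.
#'
#' @param seq An offset-subtracted [dual_channel_seq()].
#' @param baseline_window 1-based inclusive frame range used for F0; must be
#'   lit and precede the first stimulus. Default frames 31-120 (900 ms at
#'   100 Hz).
#' @return Object of class `norm_seq`: list with `donor_norm`,
#'   `acceptor_norm`, `baseline_window`, `valid_mask` and the sequence
#'   metadata.
#' @export
normalize_prestim <- function(seq, baseline_window = c(31L, 120L)) {
  stopifnot(inherits(seq, "dual_channel_seq"))
  nt <- dim(seq$donor)[3]
  bw <- check_frame_range(baseline_window, nt, "baseline_window")
  if (bw[1] <= seq$dark_frames[2]) {
    abort("baseline_window must start after the dark frames")
  }
  if (length(seq$stim_frames) && bw[2] >= min(seq$stim_frames)) {
    abort("baseline_window must end before the first stimulus frame")
  }
  bl <- bw[1]:bw[2]
  f0 <- function(x) rowMeans(x[, , bl, drop = FALSE], dims = 2)
  f0d <- f0(seq$donor); f0a <- f0(seq$acceptor)
  bad <- (f0d <= 0) | (f0a <= 0)
  valid <- seq$hemisphere_mask & !bad
  if (any(bad & seq$hemisphere_mask)) {
    warn(sprintf(
      "%d pixel(s) with non-positive baseline flagged invalid (vessel-like)",
      sum(bad & seq$hemisphere_mask)))
  }
  f0d[f0d <= 0] <- NA_real_; f0a[f0a <= 0] <- NA_real_
  structure(list(
    donor_norm = seq$donor / as.vector(f0d),
    acceptor_norm = seq$acceptor / as.vector(f0a),
    baseline_window = bw,
    valid_mask = valid,
    frame_rate = seq$frame_rate,
    dark_frames = seq$dark_frames,
    stim_frames = seq$stim_frames,
    pixel_size = seq$pixel_size
  ), class = "norm_seq")
}

# Amplitude of the discrete Fourier coefficients of pixel traces over a frame
# segment, after removing the segment mean. Returns list(freq, amp) with amp
# an (n_freq x n_pixel) matrix scaled to sinusoid amplitude units.
pixel_spectrum <- function(stack, frames, frame_rate, window = c("none", "hann")) {
  window <- match.arg(window)
  d <- dim(stack)
  n <- length(frames)
  m <- matrix(stack, ncol = d[3])[, frames, drop = FALSE]  # n_pix x n
  m <- t(m)                                                # n x n_pix
  m <- sweep(m, 2, colMeans(m), "-")
  wsum <- n
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    m <- m * w
    wsum <- sum(w)
  }
  co <- mvfft(m)
  nf <- floor(n / 2)
  amp <- 2 * Mod(co[seq_len(nf) + 1L, , drop = FALSE]) / wsum
  list(freq = seq_len(nf) * frame_rate / n, amp = amp)
}

#' Estimate the heartbeat equalisation gain by FFT
#'
#' Finds the heartbeat frequency as the dominant peak of the valid-pixel-mean
#' amplitude spectrum within a physiological band, computed over the lit
#' pre-stimulus segment, then returns the per-pixel ratio of acceptor to
#' donor amplitude at that frequency. Rescaling the donor by this gain
#' equalises the two channels' heartbeat-band amplitudes so the common-mode
#' hemodynamic artifact cancels in the ratio.
#'
#' @param norm A `norm_seq` from [normalize_prestim()].
#' @param hb_band Search band in Hz; default 5-14 Hz (head-fixed mouse heart
#'   rate).
#' @param segment Frame range for the FFT; default the baseline window.
#' @param min_prominence Minimum ratio of the band peak to the median band
#'   amplitude; below it the gain falls back to 1 everywhere with a warning.
#' @param min_amp Absolute floor (fractional F/F0 amplitude) for the band
#'   peak; below it there is no usable heartbeat artifact and the gain falls
#'   back to 1.
#' @param clip Per-pixel gains are clipped to this range (per-pixel FFT
#'   ratios are unstable at low signal-to-noise); `NULL` disables.
#' @param median_filter Apply a 3 x 3 median filter to the gain image.
#' @param mode "per_pixel" (default) or "global" (one spatial-mean gain used
#'   everywhere).
#' @param window FFT taper: "none" (default) or "hann".
#' @return List of class `hb_gain`: `gain` (matrix), `f_hb` (Hz), `fallback`
#'   (logical), `band`, plus the donor/acceptor mean amplitudes at `f_hb`.
#' @export
estimate_heartbeat_gain <- function(norm, hb_band = c(5, 14), segment = NULL,
                                    min_prominence = 3, min_amp = 1e-4,
                                    clip = c(0.2, 5),
                                    median_filter = TRUE,
                                    mode = c("per_pixel", "global"),
                                    window = c("none", "hann")) {
  stopifnot(inherits(norm, "norm_seq"))
  mode <- match.arg(mode)
  if (is.null(segment)) segment <- norm$baseline_window
  nt <- dim(norm$donor_norm)[3]
  segment <- check_frame_range(segment, nt, "segment")
  frames <- segment[1]:segment[2]
  if (hb_band[1] <= 0 || hb_band[2] >= norm$frame_rate / 2) {
    abort("hb_band must lie within (0, frame_rate / 2)")
  }
  n <- length(frames)
  if (n / norm$frame_rate * hb_band[1] < 3) {
    warn("segment shorter than 3 cycles at the low band edge; estimate may be unstable")
  }
  valid <- as.vector(norm$valid_mask)
  spD <- pixel_spectrum(norm$donor_norm, frames, norm$frame_rate, window)
  spA <- pixel_spectrum(norm$acceptor_norm, frames, norm$frame_rate, window)
  inband <- which(spD$freq >= hb_band[1] & spD$freq <= hb_band[2])
  if (!length(inband)) abort("hb_band contains no FFT bins for this segment")
  mean_amp <- rowMeans((spD$amp[inband, valid, drop = FALSE] +
                          spA$amp[inband, valid, drop = FALSE]) / 2)
  pk <- which.max(mean_amp)
  prominence <- mean_amp[pk] / stats::median(mean_amp)
  h <- dim(norm$donor_norm)[1]; w <- dim(norm$donor_norm)[2]
  # prominence Inf (zero off-peak energy) is the cleanest possible peak
  if (is.na(prominence) || prominence < min_prominence ||
      mean_amp[pk] < min_amp) {
    warn("no dominant heartbeat peak in band; falling back to gain 1")
    return(structure(list(gain = matrix(1, h, w), f_hb = NA_real_,
                          fallback = TRUE, band = hb_band,
                          donor_amp = NA_real_, acceptor_amp = NA_real_,
                          prominence = prominence),
                     class = "hb_gain"))
  }
  bin <- inband[pk]
  ampD <- matrix(spD$amp[bin, ], h, w)
  ampA <- matrix(spA$amp[bin, ], h, w)
  gain <- ampA / ampD
  gain[!is.finite(gain) | gain <= 0] <- 1
  if (!is.null(clip)) gain <- pmin(pmax(gain, clip[1]), clip[2])
  if (isTRUE(median_filter)) gain <- median3x3(gain)
  if (mode == "global") {
    g <- stats::median(gain[norm$valid_mask])
    gain <- matrix(g, h, w)
  }
  structure(list(gain = gain, f_hb = spD$freq[bin], fallback = FALSE,
                 band = hb_band,
                 donor_amp = mean(ampD[norm$valid_mask]),
                 acceptor_amp = mean(ampA[norm$valid_mask]),
                 prominence = prominence),
            class = "hb_gain")
}

# 3x3 median filter with edge replication.
median3x3 <- function(m) median3x3_cpp(m)

#' Apply the heartbeat equalisation gain to the donor channel
#'
#' Rescales the donor's fluctuations about unity by the gain image
#' (`donor' = 1 + gain * (donor - 1)`); the acceptor is the reference channel
#' and is unchanged.
#'
#' @param norm A `norm_seq`.
#' @param gain An `hb_gain` from [estimate_heartbeat_gain()] or a gain matrix.
#' @return The equalised `norm_seq` (with an `equalization` attribute
#'   recording the gain provenance).
#' @export
apply_equalization <- function(norm, gain) {
  stopifnot(inherits(norm, "norm_seq"))
  info <- NULL
  if (inherits(gain, "hb_gain")) {
    info <- gain[c("f_hb", "fallback", "band", "prominence")]
    gain <- gain$gain
  }
  norm$donor_norm <- 1 + as.vector(gain) * (norm$donor_norm - 1)
  attr(norm, "equalization") <- info
  norm
}

#' Compute the percent ratiometric voltage signal
#'
#' R = acceptor / donor per pixel per frame; R0 is R averaged over the
#' pre-stimulus window; dR/R = (R - R0) / R0, reported in percent. Dark
#' frames (no excitation light) are set to `NA`.
#'
#' @param norm An equalised `norm_seq`.
#' @param r0_window 1-based inclusive frame range for R0; default frames
#'   31-120 (90 frames, 900 ms at 100 Hz).
#' @return Object of class `ratio_seq`: `drr` (%dR/R stack), `r0_window`,
#'   `valid_mask`, `frame_rate`, `stim_frames`, `pixel_size`.
#' @export
compute_drr <- function(norm, r0_window = c(31L, 120L)) {
  stopifnot(inherits(norm, "norm_seq"))
  nt <- dim(norm$donor_norm)[3]
  r0w <- check_frame_range(r0_window, nt, "r0_window")
  lit <- setdiff(seq_len(nt), norm$dark_frames[1]:norm$dark_frames[2])
  valid <- norm$valid_mask
  # invalidate pixels whose donor is not strictly positive on lit frames
  dpos <- rowSums(norm$donor_norm[, , lit, drop = FALSE] > 0,
                  dims = 2) == length(lit)
  dpos[is.na(dpos)] <- FALSE
  newbad <- valid & !dpos
  if (any(newbad)) {
    warn(sprintf("%d pixel(s) with non-positive donor invalidated",
                 sum(newbad)))
  }
  valid <- valid & dpos
  r <- norm$acceptor_norm / norm$donor_norm
  r0 <- rowMeans(r[, , r0w[1]:r0w[2], drop = FALSE], dims = 2)
  drr <- 100 * (r / as.vector(r0) - 1)
  drr[, , norm$dark_frames[1]:norm$dark_frames[2]] <- NA_real_
  drr[!is.finite(drr)] <- NA_real_
  structure(list(drr = drr, r0_window = r0w, valid_mask = valid,
                 frame_rate = norm$frame_rate,
                 dark_frames = norm$dark_frames,
                 stim_frames = norm$stim_frames,
                 pixel_size = norm$pixel_size,
                 equalization = attr(norm, "equalization")),
            class = "ratio_seq")
}

#' @export
print.ratio_seq <- function(x, ...) {
  d <- dim(x$drr)
  cat(sprintf(
    "<ratio_seq> %d x %d px, %d frames @ %g Hz; %d valid px; R0 frames %d-%d\n",
    d[1], d[2], d[3], x$frame_rate, sum(x$valid_mask), x$r0_window[1],
    x$r0_window[2]))
  invisible(x)
}

#' One-call preprocessing of a raw trial
#'
#' Runs the full preprocessing chain: spatial binning, vessel-mask creation
#' from a lit raw donor frame, dark-offset subtraction, pre-stimulus
#' normalisation, heartbeat equalisation and ratiometric conversion.
#'
#' @param seq Raw [dual_channel_seq()].
#' @param bin_factor Spatial binning factor (4 in the standard workflow).
#' @param baseline_window,r0_window Frame ranges (defaults frames 31-120).
#' @param vessel_method,vessel_threshold Passed to [make_vessel_mask()]; the
#'   mask is computed on the binned donor frame at `baseline_window[1]`.
#' @param hb_band Heartbeat search band, Hz.
#' @param ... Further arguments to [estimate_heartbeat_gain()].
#' @return A `ratio_seq` whose `valid_mask` excludes vessels, plus provenance
#'   in `$equalization` and `$vessel_frac`.
#' @export
preprocess_trial <- function(seq, bin_factor = 4L,
                             baseline_window = c(31L, 120L),
                             r0_window = c(31L, 120L),
                             vessel_method = "fixed", vessel_threshold = 500,
                             hb_band = c(5, 14), ...) {
  stopifnot(inherits(seq, "dual_channel_seq"))
  b <- bin_sequence(seq, bin_factor)
  vmask <- make_vessel_mask(b$donor[, , baseline_window[1]],
                            method = vessel_method,
                            threshold = vessel_threshold)
  b$hemisphere_mask <- b$hemisphere_mask & !vmask
  b <- subtract_dark_offset(b)
  nrm <- normalize_prestim(b, baseline_window)
  g <- estimate_heartbeat_gain(nrm, hb_band = hb_band, ...)
  nrm <- apply_equalization(nrm, g)
  out <- compute_drr(nrm, r0_window)
  out$vessel_frac <- mean(vmask)
  out
}
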