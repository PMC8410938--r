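# Ground-truth voltage time courses and geometry for the forward model.

#' Generate the hidden voltage ground truth for one trial
#'
#' Samples the per-region voltage time course on the frame grid. Each
#' stimulus contributes, per region, a depolarising difference-of-exponentials
#' kernel (zero before stimulus onset + onset delay, unit peak scaled to
#' `A_dep`, peaking at `peak_latency` after the stimulus) and a slower
#' negative kernel of amplitude `A_hyp` peaking at `hyp_peak_time`; kernels of
#' successive stimuli sum linearly, scaled by the per-stimulus factors. With
#' `latency_jitter_sd > 0` the whole kernel of a trial is shifted by a
#' Gaussian latency jitter (truncated so the onset stays positive).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Object of class `voltage_truth`: `V` (regions x frames matrix, %),
#'   `time_ms` (frame times relative to the first stimulus), `regions`,
#'   per-region `peak_amp` / `peak_time_ms` (analytic, first stimulus),
#'   `label_binned` / `label_raw` region membership images, `vessel_mask`
#'   (raw), `layout`, `movement_epochs` (filled by the session generator) and
#'   the config.
#' @export
generate_voltage_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  dt <- frame_dt_ms(config$frame_rate)
  nt <- config$n_frames
  s1 <- config$stim_frames[1]
  regions <- names(config$region_kernels)
  V <- matrix(0, nrow = length(regions), ncol = nt,
              dimnames = list(regions, NULL))
  jitter <- if (config$latency_jitter_sd > 0)
    rnorm(1, 0, config$latency_jitter_sd) else 0
  peak_amp <- setNames(numeric(length(regions)), regions)
  peak_time <- setNames(rep(NA_real_, length(regions)), regions)
  for (r in regions) {
    kk <- config$region_kernels[[r]]
    onset <- max(kk$onset_delay + jitter, 0.5 * dt)
    vr <- numeric(nt)
    for (j in seq_along(config$stim_frames)) {
      sj <- config$stim_frames[j]
      trel <- frame_time_ms(seq_len(nt), sj, config$frame_rate)
      fac <- config$stim_factors[j]
      if (kk$A_dep > 0) {
        rise <- solve_rise_tau(kk$peak_latency - kk$onset_delay, kk$decay_tau)
        vr <- vr + fac * kk$A_dep * doe_kernel(trel, onset, rise, kk$decay_tau)
      }
      if (kk$A_hyp > 0) {
        hyp_onset <- max(kk$hyp_onset + jitter, 0.5 * dt)
        hrise <- solve_rise_tau(kk$hyp_peak_time - kk$hyp_onset,
                                kk$hyp_decay_tau)
        vr <- vr - fac * kk$A_hyp *
          doe_kernel(trel, hyp_onset, hrise, kk$hyp_decay_tau)
      }
    }
    V[r, ] <- vr
    if (kk$A_dep > 0) {
      peak_amp[r] <- kk$A_dep * config$stim_factors[1]
      peak_time[r] <- onset + (kk$peak_latency - kk$onset_delay)
    }
  }

  binned_shape <- config$raw_shape %/% config$bin_factor
  layout <- default_atlas_layout(binned_shape,
                                 pixel_size = config$pixel_size_um)
  label_binned <- rasterize_atlas(layout, binned_shape)
  # ground-truth membership lives on the analysis (binned) grid and is
  # replicated to raw pixels, so recovery error reflects the pipeline, not
  # partial-volume mixing at region borders
  up <- matrix(1L, config$bin_factor, config$bin_factor)
  label_raw <- kronecker(unclass(label_binned), up)
  vessel_mask <- render_vessel_mask(config)

  structure(list(
    V = V,
    time_ms = frame_time_ms(seq_len(nt), s1, config$frame_rate),
    regions = regions,
    peak_amp = peak_amp,
    peak_time_ms = peak_time,
    latency_jitter = jitter,
    label_binned = label_binned,
    label_raw = label_raw,
    vessel_mask = vessel_mask,
    layout = layout,
    movement_epochs = list(),
    config = config
  ), class = "voltage_truth")
}

# Rasterise the configured vessel segments onto the raw grid.
render_vessel_mask <- function(config) {
  h <- config$raw_shape[1]; w <- config$raw_shape[2]
  mask <- matrix(FALSE, h, w)
  pr <- rep(seq_len(h), times = w)
  pc <- rep(seq_len(w), each = h)
  for (seg in config$vessel_spec) {
    a <- c(seg$from[1] * h, seg$from[2] * w)
    b <- c(seg$to[1] * h, seg$to[2] * w)
    half <- max(seg$width_frac * h, 1) / 2
    vr <- b[1] - a[1]; vc <- b[2] - a[2]
    len2 <- vr^2 + vc^2
    tt <- pmin(1, pmax(0, ((pr - a[1]) * vr + (pc - a[2]) * vc) / len2))
    d2 <- (pr - (a[1] + tt * vr))^2 + (pc - (a[2] + tt * vc))^2
    mask <- mask | matrix(d2 <= half^2, h, w)
  }
  mask
}

#' @export
print.voltage_truth <- function(x, ...) {
  cat(sprintf("<voltage_truth> %d regions x %d frames; stim at %s\n",
              nrow(x$V), ncol(x$V),
              paste(x$config$stim_frames, collapse = ",")))
  dep <- x$peak_amp[x$peak_amp > 0]
  if (length(dep)) {
    cat(sprintf("  depolarising truth: %s\n",
                paste(sprintf("%s %.3f%% @ %.1f ms", names(dep), dep,
                              x$peak_time_ms[names(dep)]), collapse = "; ")))
  }
  invisible(x)
}

#' @describeIn generate_voltage_truth Tidy the truth time courses into a
#'   long tibble (region, frame, time_ms, voltage_pct).
#' @param x A `voltage_truth`.
#' @param ... Unused.
#' @export
tidy.voltage_truth <- function(x, ...) {
  tibble::tibble(
    region = rep(rownames(x$V), times = ncol(x$V)),
    frame = rep(seq_len(ncol(x$V)), each = nrow(x$V)),
    time_ms = rep(x$time_ms, each = nrow(x$V)),
    voltage_pct = as.vector(x$V)
  )
}
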