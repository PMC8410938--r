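# Trial-averaged, bregma-aligned per-pixel voltage maps.

#' Baseline-subtracted voltage map for one trial
#'
#' Subtracts, per pixel, the mean %dR/R over the 10 frames preceding the
#' stimulus (100 ms) from every frame: dR = dR/R - baseline. Invalid
#' (vessel/out-of-window) pixels are `NA`, never rendered as zero.
#'
#' @param ratio A `ratio_seq`.
#' @param stim_frame Stimulus frame; default the first in the sequence.
#' @param layout An [atlas_layout()] supplying the alignment reference
#'   (bregma, midline); optional but required for [average_aligned_maps()].
#' @param baseline_frames Frames averaged for the per-pixel baseline.
#' @return Object of class `voltage_map`: `dr` stack (%), `n_trials` image,
#'   `stim_frame`, `frame_rate`, `pixel_size`, `layout`, `scale_limits`
#'   (default +/- 0.5 %).
#' @export
trial_map <- function(ratio, stim_frame = ratio$stim_frames[1], layout = NULL,
                      baseline_frames = 10L) {
  stopifnot(inherits(ratio, "ratio_seq"))
  nt <- dim(ratio$drr)[3]
  bidx <- (stim_frame - baseline_frames):(stim_frame - 1L)
  if (min(bidx) < 1) abort("missing pre-stimulus baseline frames")
  base <- rowMeans(ratio$drr[, , bidx, drop = FALSE], dims = 2)
  dr <- ratio$drr - as.vector(base)
  inv <- !ratio$valid_mask
  if (any(inv)) dr[array(inv, dim(dr))] <- NA_real_
  structure(list(dr = dr,
                 n_trials = matrix(as.integer(ratio$valid_mask),
                                   nrow(ratio$valid_mask)),
                 stim_frame = as.integer(stim_frame),
                 frame_rate = ratio$frame_rate,
                 pixel_size = ratio$pixel_size,
                 layout = layout,
                 scale_limits = c(-0.5, 0.5)),
            class = "voltage_map")
}

#' @export
print.voltage_map <- function(x, ...) {
  d <- dim(x$dr)
  cat(sprintf(
    "<voltage_map> %d x %d px, %d frames; max |dR| %.3f %%; n_trials up to %d\n",
    d[1], d[2], d[3], max(abs(x$dr), na.rm = TRUE), max(x$n_trials)))
  invisible(x)
}

# Rigid alignment of one frame stack: translate bregma to the common origin
# and rotate the midline to vertical, nearest-neighbour resampling (no
# interpolation, preserving the no-additional-filtering contract).
align_stack_nn <- function(stack, bregma, angle_deg, out_shape, out_bregma) {
  h <- out_shape[1]; w <- out_shape[2]
  pr <- rep(seq_len(h), times = w) - out_bregma[1]
  pc <- rep(seq_len(w), each = h) - out_bregma[2]
  th <- -angle_deg * pi / 180  # inverse rotation: output -> source
  cs <- cos(th); sn <- sin(th)
  sr <- round(bregma[1] + pr * cs - pc * sn)
  sc <- round(bregma[2] + pr * sn + pc * cs)
  ok <- sr >= 1 & sr <= dim(stack)[1] & sc >= 1 & sc <= dim(stack)[2]
  idx <- ifelse(ok, sr + (sc - 1) * dim(stack)[1], NA_integer_)
  nt <- dim(stack)[3]
  m <- matrix(stack, ncol = nt)
  out <- m[idx, , drop = FALSE]
  array(out, c(h, w, nt))
}

#' Average voltage maps across trials after bregma/midline alignment
#'
#' Rigidly aligns every map (translation of bregma to a common origin,
#' rotation of the midline to vertical, nearest-neighbour resampling) and
#' averages per pixel over the trials contributing to that pixel. No spatial
#' or temporal filtering of any kind is applied.
#'
#' @param maps List of `voltage_map`s (each needs a `layout`, or pass
#'   `layouts`).
#' @param layouts Optional list of [atlas_layout()]s overriding the maps'
#'   own.
#' @param out_shape Output grid c(rows, cols); default the first map's.
#' @param out_bregma Common bregma position on the output grid; default the
#'   first layout's.
#' @return A `voltage_map` whose `n_trials` image counts contributing trials
#'   per pixel; pixels with no contributions are `NA` with `n_trials = 0`.
#' @export
average_aligned_maps <- function(maps, layouts = NULL, out_shape = NULL,
                                 out_bregma = NULL) {
  if (!length(maps)) abort("need at least one map")
  if (is.null(layouts)) layouts <- lapply(maps, `[[`, "layout")
  if (any(vapply(layouts, is.null, logical(1)))) {
    abort("every map needs alignment metadata (a layout)")
  }
  if (is.null(out_shape)) out_shape <- dim(maps[[1]]$dr)[1:2]
  if (is.null(out_bregma)) out_bregma <- layouts[[1]]$bregma_px
  nt <- dim(maps[[1]]$dr)[3]
  sum_arr <- array(0, c(out_shape, nt))
  cnt_arr <- array(0L, c(out_shape, nt))
  for (i in seq_along(maps)) {
    al <- align_stack_nn(maps[[i]]$dr, layouts[[i]]$bregma_px,
                         layouts[[i]]$midline_angle, out_shape, out_bregma)
    ok <- !is.na(al)
    al[!ok] <- 0
    sum_arr <- sum_arr + al
    cnt_arr <- cnt_arr + ok
  }
  avg <- sum_arr / cnt_arr
  avg[cnt_arr == 0L] <- NA_real_
  n_img <- matrix(apply(cnt_arr, c(1, 2), max), out_shape[1])
  out_layout <- layouts[[1]]
  out_layout$bregma_px <- as.numeric(out_bregma)
  out_layout$midline_angle <- 0
  structure(list(dr = avg, n_trials = n_img,
                 stim_frame = maps[[1]]$stim_frame,
                 frame_rate = maps[[1]]$frame_rate,
                 pixel_size = maps[[1]]$pixel_size,
                 layout = out_layout,
                 scale_limits = maps[[1]]$scale_limits),
            class = "voltage_map")
}

#' Tidy a voltage map into a long tibble
#'
#' @param x A `voltage_map`.
#' @param times_ms Frame times (ms relative to the stimulus) to include;
#'   default all frames.
#' @param ... Unused.
#' @return Tibble: `row`, `col`, `frame`, `time_ms`, `dr_pct`, `n_trials`.
#' @export
tidy.voltage_map <- function(x, times_ms = NULL, ...) {
  nt <- dim(x$dr)[3]
  t_all <- frame_time_ms(seq_len(nt), x$stim_frame, x$frame_rate)
  frames <- if (is.null(times_ms)) seq_len(nt) else {
    vapply(times_ms, function(tm) which.min(abs(t_all - tm)), integer(1))
  }
  h <- dim(x$dr)[1]; w <- dim(x$dr)[2]
  dplyr::bind_rows(lapply(frames, function(f) {
    tibble::tibble(row = rep(seq_len(h), times = w),
                   col = rep(seq_len(w), each = h),
                   frame = f, time_ms = t_all[f],
                   dr_pct = as.vector(x$dr[, , f]),
                   n_trials = as.vector(x$n_trials))
  }))
}

#' @export
glance.voltage_map <- function(x, ...) {
  tibble::tibble(
    n_frames = dim(x$dr)[3],
    n_pixels = prod(dim(x$dr)[1:2]),
    n_trials_max = max(x$n_trials),
    peak_dr_pct = max(x$dr, na.rm = TRUE),
    trough_dr_pct = min(x$dr, na.rm = TRUE),
    pixel_size_um = x$pixel_size
  )
}

#' Plot selected frames of a voltage map
#'
#' Renders frames with the standard diverging convention: depolarised pixels
#' red saturating at +0.5 % dR/R, hyperpolarised pixels blue at -0.5 %,
#' white at zero; bregma marked; pixels with no contributing trials are
#' blank.
#'
#' @param object A `voltage_map`.
#' @param times_ms Frame times (ms) to show; default c(-30, 0, 60, 120, 180).
#' @param ... Unused.
#' @return A ggplot object (facetted by frame time).
#' @export
autoplot.voltage_map <- function(object, times_ms = c(-30, 0, 60, 120, 180),
                                 ...) {
  df <- tidy(object, times_ms = times_ms)
  lim <- object$scale_limits
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$dr_pct)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = lim, oob = scales::squish,
                         name = "%ΔR/R") +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    facet_wrap(~time_ms, labeller = ggplot2::label_both, nrow = 1) +
    theme_minimal() +
    labs(x = NULL, y = NULL)
  if (!is.null(object$layout)) {
    b <- object$layout$bregma_px
    p <- p + annotate("point", x = b[2], y = b[1], shape = 22,
                      fill = "white", colour = "black", size = 2)
  }
  p
}

#' Write rendered map frames to PNG files
#'
#' @param map A `voltage_map`.
#' @param times_ms Frame times to render.
#' @param out_dir Output directory (created if missing).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the written file paths.
#' @export
render_map_frames <- function(map, times_ms = c(-30, 0, 60, 120, 180),
                              out_dir = ".", width = 4, height = 3,
                              dpi = 150) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(times_ms))
  for (i in seq_along(times_ms)) {
    p <- autoplot(map, times_ms = times_ms[i])
    paths[i] <- file.path(out_dir, sprintf("map_%+04dms.png",
                                           round(times_ms[i])))
    ggsave(paths[i], p, width = width, height = height, dpi = dpi)
  }
  invisible(paths)
}
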