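# Plot helpers and small tidiers for tabular results.

#' Plot region-averaged voltage traces
#'
#' @param traces Tibble from [region_trace()] / [region_traces()] (optionally
#'   with a `trial_id` column, drawn as thin per-trial lines plus the
#'   across-trial mean).
#' @param regions Subset of regions to show; default all.
#' @return A ggplot object: %dR/R versus time with the stimulus at 0 ms.
#' @export
plot_region_traces <- function(traces, regions = NULL) {
  if (!is.null(regions)) {
    traces <- dplyr::filter(traces, .data$region %in% regions)
  }
  has_trials <- "trial_id" %in% names(traces) &&
    length(unique(traces$trial_id)) > 1
  p <- ggplot(traces, aes(x = .data$time_ms, y = .data$drr_pct,
                          colour = .data$region))
  if (has_trials) {
    p <- p +
      geom_line(aes(group = interaction(.data$region, .data$trial_id)),
                alpha = 0.2) +
      geom_line(data = traces |>
                  dplyr::group_by(.data$region, .data$time_ms) |>
                  dplyr::summarise(drr_pct = mean(.data$drr_pct),
                                   .groups = "drop"),
                linewidth = 0.9)
  } else {
    p <- p + geom_line()
  }
  p + geom_vline(xintercept = 0, linetype = "dashed") +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "time from stimulus (ms)", y = "%ΔR/R", colour = NULL) +
    theme_minimal()
}

#' @describeIn compute_drr One-row summary of a ratio sequence (valid-pixel
#'   count, detected heartbeat frequency, baseline residual).
#' @param x A `ratio_seq`.
#' @param ... Unused.
#' @export
glance.ratio_seq <- function(x, ...) {
  r0 <- x$r0_window[1]:x$r0_window[2]
  base_resid <- max(abs(rowMeans(x$drr[, , r0, drop = FALSE],
                                 dims = 2)[x$valid_mask]))
  tibble::tibble(
    n_pixels = prod(dim(x$drr)[1:2]),
    n_valid = sum(x$valid_mask),
    n_frames = dim(x$drr)[3],
    frame_rate = x$frame_rate,
    f_hb_hz = x$equalization$f_hb %||% NA_real_,
    equalization_fallback = isTRUE(x$equalization$fallback),
    baseline_residual_pct = base_resid
  )
}
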