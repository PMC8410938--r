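# Pipeline settings as a single YAML document.

#' Read pipeline settings from YAML
#'
#' All analysis windows and thresholds (binning factor, baseline/R0 windows,
#' vessel threshold, heartbeat band, movement separator) live in one YAML
#' file; fields omitted from a user file fall back to the packaged defaults.
#'
#' @param path YAML file; `NULL` for the packaged defaults.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "pipeline_defaults.yaml",
                                          package = "widevolt"))
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    warn(sprintf("ignoring unknown pipeline settings: %s",
                 paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, user[intersect(names(user), names(defaults))])
}

#' Write a ratio sequence as a 32-bit float TIFF with provenance
#'
#' The %dR/R stack goes to a float multi-frame TIFF (invalid/undefined
#' pixels filled at the stack minimum, flagged in the sidecar) and the
#' processing provenance (windows, detected heartbeat frequency, valid-pixel
#' count) to a JSON sidecar.
#'
#' @param ratio A `ratio_seq` from [compute_drr()] / [preprocess_trial()].
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_ratio_tiff <- function(ratio, path) {
  stopifnot(inherits(ratio, "ratio_seq"))
  arr <- ratio$drr
  arr[is.na(arr)] <- NaN
  arr[array(!ratio$valid_mask, dim(arr))] <- NaN
  finite <- arr[is.finite(arr)]
  arr[!is.finite(arr)] <- if (length(finite)) min(finite) else 0
  write_stack_tiff(arr, path, float = TRUE)
  jsonlite::write_json(list(
    r0_window = ratio$r0_window,
    dark_frames = ratio$dark_frames,
    stim_frames = ratio$stim_frames,
    frame_rate = ratio$frame_rate,
    pixel_size_um = ratio$pixel_size,
    n_valid = sum(ratio$valid_mask),
    f_hb_hz = ratio$equalization$f_hb %||% NA,
    equalization_fallback = isTRUE(ratio$equalization$fallback),
    valid_mask_note = "pixels outside valid_mask written at the stack minimum; consult n_valid and the mask"
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
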