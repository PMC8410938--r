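# Session-level orchestration: stack file formats, manifests, the end-to-end
# pipeline and tidy output writers.

#' Write a frame stack as a multi-frame 16-bit TIFF
#'
#' Counts are stored in a 16-bit container (12-bit data); float stacks (e.g.
#' %dR/R maps) can be written as 32-bit float TIFF with `float = TRUE`.
#'
#' @param stack 3-d array [rows, cols, frames].
#' @param path Output file.
#' @param float Write 32-bit float samples instead of 16-bit integer counts.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, float = FALSE) {
  check_stack(stack)
  frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (float) {
    # the TIFF writer stores samples in [0, 1]; record the affine scaling in
    # a JSON sidecar (<path>.scale.json) so float stacks round-trip
    lo <- min(stack); hi <- max(stack)
    scale <- if (hi > lo) hi - lo else 1
    frames <- lapply(frames, function(m) (m - lo) / scale)
    jsonlite::write_json(list(lo = lo, scale = scale),
                         paste0(path, ".scale.json"), auto_unbox = TRUE,
                         digits = NA)
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    frames <- lapply(frames, function(m) m / 65535)
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a multi-frame TIFF stack written by [write_stack_tiff()]
#'
#' @param path TIFF file.
#' @param float Stack was written as 32-bit float.
#' @return 3-d array [rows, cols, frames].
#' @export
read_stack_tiff <- function(path, float = FALSE) {
  if (!file.exists(path)) abort(sprintf("missing stack file: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(unlist(frames), c(dim(frames[[1]])[1:2], length(frames)))
  if (float) {
    sidecar <- paste0(path, ".scale.json")
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar)
      arr <- arr * sc$scale + sc$lo
    }
  } else {
    arr <- round(arr * 65535)
  }
  arr
}

#' Generate and write a complete synthetic session
#'
#' Writes, per trial, donor/acceptor/behaviour multi-frame TIFFs, a YAML
#' session manifest and a JSON ground-truth sidecar sufficient to score every
#' downstream metric. Deterministic given the seed (per-trial seeds are
#' derived reproducibly).
#'
#' @param config A [synthetic_config()].
#' @param n_trials Number of trials (the standard session is 25 trials).
#' @param out_dir Session directory (created).
#' @param seed Session seed.
#' @param movement_trials Optional named list: trial index (as character or
#'   integer) -> list of movement epochs for that trial's behaviour stack.
#' @param session_id,mouse_id,condition Manifest metadata.
#' @return The manifest path, invisibly.
#' @export
generate_session <- function(config, n_trials = 25L, out_dir, seed = config$seed,
                             movement_trials = list(),
                             session_id = "synthetic-session",
                             mouse_id = "sim01", condition = "control") {
  stopifnot(inherits(config, "synthetic_config"), n_trials >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  ep_for <- function(i) {
    movement_trials[[as.character(i)]] %||% list()
  }
  trials <- list()
  truth_all <- list()
  interstim <- if (length(config$stim_frames) > 1) {
    diff(config$stim_frames)[1] * frame_dt_ms(config$frame_rate)
  } else NULL
  stim_type <- if (length(config$stim_frames) > 1 &&
                   config$stimulus == "paw") "paw_pair" else config$stimulus
  for (i in seq_len(n_trials)) {
    tseed <- derive_seed(seed, i)
    sim <- simulate_trial(config, seed = tseed, movement_epochs = ep_for(i))
    id <- sprintf("trial_%03d", i)
    paths <- file.path(out_dir, paste0(id, c("_donor.tif", "_acceptor.tif",
                                             "_behavior.tif")))
    write_stack_tiff(sim$seq$donor, paths[1])
    write_stack_tiff(sim$seq$acceptor, paths[2])
    write_stack_tiff(sim$behavior, paths[3])
    binned_shape <- config$raw_shape %/% config$bin_factor
    layout <- sim$truth$layout
    trials[[i]] <- list(
      trial_id = id,
      stimulus = stim_type,
      interstim_ms = interstim,
      stim_frames = as.integer(config$stim_frames),
      donor = basename(paths[1]), acceptor = basename(paths[2]),
      behavior = basename(paths[3]),
      bregma_px = as.numeric(layout$bregma_px),
      midline_angle = layout$midline_angle,
      seed = tseed
    )
    truth_all[[id]] <- list(
      V = sim$truth$V,
      regions = sim$truth$regions,
      peak_amp = as.list(sim$truth$peak_amp),
      peak_time_ms = as.list(sim$truth$peak_time_ms),
      latency_jitter = sim$truth$latency_jitter,
      movement_epochs = ep_for(i),
      vessel_frac = mean(sim$truth$vessel_mask)
    )
  }
  manifest <- list(
    session_id = session_id, mouse_id = mouse_id, condition = condition,
    frame_rate = config$frame_rate, n_frames = config$n_frames,
    dark_frames = as.integer(config$dark_frames),
    bin_factor = config$bin_factor,
    pixel_size_um = config$pixel_size_um,
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("widevolt")),
    trials = trials
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  jsonlite::write_json(truth_all, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(manifest_path)
}

#' Load a session manifest and validate its trials
#'
#' Schema violations are reported with field paths; stack files are checked
#' for existence at load and for frame count on first read.
#'
#' @param path Manifest YAML file or session directory.
#' @return Object of class `session_manifest` (the manifest list plus
#'   `dir`), with a `read_trial(i)` accessor attached.
#' @export
load_session <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
  if (!file.exists(path)) abort(sprintf("missing manifest: %s", path))
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  for (field in c("session_id", "frame_rate", "n_frames", "dark_frames",
                  "trials")) {
    if (is.null(m[[field]])) {
      abort(sprintf("manifest field '%s' is missing", field))
    }
  }
  ids <- vapply(m$trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) abort("trials: duplicated trial_id")
  for (i in seq_along(m$trials)) {
    tr <- m$trials[[i]]
    for (f in c("donor", "acceptor", "behavior")) {
      fp <- file.path(dir, tr[[f]])
      if (!file.exists(fp)) {
        abort(sprintf("trials[%d] (%s): missing file '%s' [missing-file]",
                      i, tr$trial_id, tr[[f]]))
      }
    }
    if (!is.null(tr$interstim_ms) && length(tr$stim_frames) < 2) {
      abort(sprintf(
        "trials[%d]: interstim_ms present but fewer than 2 stim_frames", i))
    }
  }
  m$dir <- dir
  structure(m, class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> %s (%s, %s): %d trials @ %g Hz\n",
              x$session_id, x$mouse_id %||% "?", x$condition %||% "?",
              length(x$trials), x$frame_rate))
  invisible(x)
}

#' Read one trial's stacks from a loaded session
#'
#' Validates the declared frame count against the files.
#'
#' @param manifest A [load_session()] result.
#' @param i Trial index.
#' @return List: `seq` (a [dual_channel_seq()]), `behavior` stack, `trial`
#'   (manifest entry).
#' @export
read_trial <- function(manifest, i) {
  stopifnot(inherits(manifest, "session_manifest"))
  tr <- manifest$trials[[i]]
  donor <- read_stack_tiff(file.path(manifest$dir, tr$donor))
  acceptor <- read_stack_tiff(file.path(manifest$dir, tr$acceptor))
  behavior <- read_stack_tiff(file.path(manifest$dir, tr$behavior))
  for (nm in c("donor", "acceptor")) {
    nf <- dim(get(nm))[3]
    if (nf != manifest$n_frames) {
      abort(sprintf("%s (%s): %d frames, manifest declares %d [frame-count]",
                    nm, tr$trial_id, nf, manifest$n_frames))
    }
  }
  seq <- dual_channel_seq(donor, acceptor,
                          frame_rate = manifest$frame_rate,
                          dark_frames = unlist(manifest$dark_frames),
                          stim_frames = unlist(tr$stim_frames),
                          pixel_size = manifest$pixel_size_um /
                            (manifest$bin_factor %||% 4))
  list(seq = seq, behavior = behavior, trial = tr)
}

#' Run the full analysis pipeline over a session
#'
#' Stage order: movement classification -> (quiet trials only) preprocessing
#' -> vessel masking / atlas registration -> region traces -> response
#' metrics (and paired-pulse adaptation for paired-stimulus trials) -> trial
#' maps and their bregma-aligned average. Any stage error aborts the trial,
#' not the session; failed trials are enumerated in the provenance.
#'
#' @param manifest A [load_session()] result (or a path, which is loaded).
#' @param calib Optional [calibrate_noise()] result; if `NULL` a stationary
#'   synthetic reference with matching geometry is generated from the
#'   manifest seed.
#' @param layout Optional [atlas_layout()] overriding per-trial manifest
#'   alignment.
#' @param settings Pipeline settings: a list from [read_pipeline_config()]
#'   or a YAML path; `NULL` uses the packaged defaults. Explicit arguments
#'   below override it.
#' @param include_movement Analyse movement-labelled trials too (they are
#'   still flagged; the default FALSE excludes them, the quiet-trial
#'   contract).
#' @param bin_factor,baseline_window,r0_window,vessel_threshold,hb_band
#'   Preprocessing settings (see [preprocess_trial()]).
#' @param movement_threshold_pct Changed-pixel threshold, %.
#' @return Object of class `session_results`: tibbles `movement`, `traces`,
#'   `metrics`, `adaptation`, the averaged `map`, and `provenance`.
#' @export
run_pipeline <- function(manifest, calib = NULL, layout = NULL,
                         settings = NULL, include_movement = NULL,
                         bin_factor = NULL, baseline_window = NULL,
                         r0_window = NULL, vessel_threshold = NULL,
                         hb_band = NULL, movement_threshold_pct = NULL) {
  if (is.character(manifest)) manifest <- load_session(manifest)
  s <- if (is.character(settings)) read_pipeline_config(settings) else
    settings %||% read_pipeline_config()
  include_movement <- include_movement %||% s$include_movement
  baseline_window <- baseline_window %||% unlist(s$baseline_window)
  r0_window <- r0_window %||% unlist(s$r0_window)
  vessel_threshold <- vessel_threshold %||% s$vessel_threshold
  hb_band <- hb_band %||% unlist(s$hb_band)
  movement_threshold_pct <- movement_threshold_pct %||%
    s$movement_threshold_pct
  bin_factor <- bin_factor %||% manifest$bin_factor %||% s$bin_factor
  t0 <- Sys.time()
  if (is.null(calib)) calib <- stationary_reference_calibration(manifest)
  movement <- list(); traces <- list(); metrics <- list()
  adaptation <- list(); maps <- list(); failed <- list()

  process_one <- function(i) {
    id <- manifest$trials[[i]]$trial_id
    tr <- read_trial(manifest, i)
    s1 <- tr$seq$stim_frames[1]
    mv <- classify_movement(tr$behavior, s1, calib,
                            threshold_pct = movement_threshold_pct)
    mv$trial_id <- id
    if (mv$label == "movement" && !include_movement) {
      return(list(movement = mv))
    }
    ratio <- preprocess_trial(tr$seq, bin_factor = bin_factor,
                              baseline_window = baseline_window,
                              r0_window = r0_window,
                              vessel_threshold = vessel_threshold,
                              hb_band = hb_band)
    lay <- layout %||% atlas_layout(
      bregma_px = unlist(tr$trial$bregma_px),
      midline_angle = tr$trial$midline_angle %||% 0,
      pixel_size = ratio$pixel_size)
    labels <- rasterize_atlas(lay, dim(ratio$drr)[1:2])
    trc <- region_traces(ratio, labels)
    trc$trial_id <- id
    stim_frames <- tr$seq$stim_frames
    met <- dplyr::bind_rows(lapply(unique(trc$region), function(rg) {
      response_metrics(dplyr::filter(trc, .data$region == rg),
                       s1, manifest$frame_rate, region = rg, trial_id = id)
    }))
    adp <- if (length(stim_frames) >= 2) {
      dplyr::bind_rows(lapply(unique(trc$region), function(rg) {
        paired_pulse(dplyr::filter(trc, .data$region == rg),
                     stim_frames[1:2], manifest$frame_rate,
                     region = rg, trial_id = id)
      }))
    }
    list(movement = mv, traces = trc, metrics = met, adaptation = adp,
         map = trial_map(ratio, s1, layout = lay))
  }

  for (i in seq_along(manifest$trials)) {
    id <- manifest$trials[[i]]$trial_id
    out <- tryCatch(process_one(i), error = function(e) conditionMessage(e))
    if (is.character(out)) {
      failed[[id]] <- out
      next
    }
    movement[[id]] <- out$movement
    if (!is.null(out$traces)) traces[[id]] <- out$traces
    if (!is.null(out$metrics)) metrics[[id]] <- out$metrics
    if (!is.null(out$adaptation)) adaptation[[id]] <- out$adaptation
    if (!is.null(out$map)) maps[[id]] <- out$map
  }
  avg_map <- if (length(maps)) average_aligned_maps(unname(maps)) else NULL
  structure(list(
    movement = dplyr::bind_rows(movement),
    traces = dplyr::bind_rows(traces),
    metrics = dplyr::bind_rows(metrics),
    adaptation = dplyr::bind_rows(adaptation),
    map = avg_map,
    provenance = list(
      session_id = manifest$session_id,
      package_version = as.character(utils::packageVersion("widevolt")),
      n_trials = length(manifest$trials),
      n_quiet = sum(dplyr::bind_rows(movement)$label == "quiet"),
      failed_trials = failed,
      settings = list(bin_factor = bin_factor,
                      baseline_window = as.integer(baseline_window),
                      r0_window = as.integer(r0_window),
                      vessel_threshold = vessel_threshold,
                      hb_band = hb_band,
                      movement_threshold_pct = movement_threshold_pct,
                      include_movement = include_movement),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  ), class = "session_results")
}

# Stationary-reference calibration with the session's behaviour geometry,
# generated from the manifest seed (stands in for the fabric-mouse recording
# when none is supplied). The reference is much longer than a trial: with a
# max-over-N-frames threshold the chance of a fresh noise sample beating the
# calibrated maximum is about 1/(N+1) per pixel, so N must be large for the
# stationary false-change rate to sit well below the 0.5 % separator.
stationary_reference_calibration <- function(manifest, n_frames = 1000L) {
  beh_shape <- dim(read_stack_tiff(
    file.path(manifest$dir, manifest$trials[[1]]$behavior)))[1:2]
  cfg <- synthetic_config(n_frames = n_frames,
                          raw_shape = c(8L, 8L),
                          dark_frames = c(1L, 2L),
                          stim_frames = n_frames %/% 2,
                          stimulus = "none", vessel_spec = list(),
                          behavior_shape = beh_shape,
                          seed = derive_seed(manifest$seed %||% 1L, 999))
  stack <- generate_behavior_stack(cfg, movement_epochs = list(),
                                   seed = cfg$seed)
  calibrate_noise(stack, ref_frame = cfg$stim_frames[1])
}

#' @export
print.session_results <- function(x, ...) {
  cat(sprintf(
    "<session_results> %s: %d/%d quiet trials; %d metric rows; %d failed\n",
    x$provenance$session_id, x$provenance$n_quiet, x$provenance$n_trials,
    nrow(x$metrics), length(x$provenance$failed_trials)))
  invisible(x)
}

#' @export
glance.session_results <- function(x, ...) {
  tibble::tibble(
    n_trials = x$provenance$n_trials,
    n_quiet = x$provenance$n_quiet,
    n_included = sum(x$metrics$included),
    n_failed = length(x$provenance$failed_trials),
    elapsed_s = x$provenance$elapsed_s
  )
}

#' @describeIn run_pipeline Tidy the per-trial, per-region metrics table.
#' @param x A `session_results`.
#' @param ... Unused.
#' @export
tidy.session_results <- function(x, ...) x$metrics

#' Write session results to tidy files
#'
#' Writes metrics, traces, adaptation and movement tables as CSV, the
#' averaged map as a 32-bit float TIFF with a JSON sidecar, provenance JSON
#' and a data dictionary documenting columns and units.
#'
#' @param results A `session_results`.
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_outputs <- function(results, out_dir) {
  stopifnot(inherits(results, "session_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metrics = file.path(out_dir, "metrics.csv"),
             traces = file.path(out_dir, "region_traces.csv"),
             adaptation = file.path(out_dir, "adaptation.csv"),
             movement = file.path(out_dir, "movement.csv"),
             provenance = file.path(out_dir, "provenance.json"),
             dictionary = file.path(out_dir, "data_dictionary.csv"))
  if (nrow(results$metrics) == 0) {
    warn("no included trials; writing header-only metrics table")
  }
  readr::write_csv(results$metrics, paths["metrics"])
  readr::write_csv(results$traces, paths["traces"])
  readr::write_csv(results$adaptation, paths["adaptation"])
  readr::write_csv(results$movement, paths["movement"])
  jsonlite::write_json(results$provenance, paths["provenance"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  readr::write_csv(data_dictionary(), paths["dictionary"])
  if (!is.null(results$map)) {
    mp <- file.path(out_dir, "average_map.tif")
    arr <- results$map$dr
    arr[is.na(arr)] <- 0
    write_stack_tiff(arr, mp, float = TRUE)
    jsonlite::write_json(
      list(stim_frame = results$map$stim_frame,
           frame_rate = results$map$frame_rate,
           pixel_size_um = results$map$pixel_size,
           bregma_px = results$map$layout$bregma_px,
           scale_limits_pct = results$map$scale_limits,
           n_trials_max = max(results$map$n_trials)),
      file.path(out_dir, "average_map.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, map = mp)
  }
  invisible(paths)
}

data_dictionary <- function() {
  tibble::tribble(
    ~table, ~column, ~units, ~description,
    "metrics", "peak_amp", "%dR/R", "evoked depolarisation peak relative to the 10-frame pre-stimulus baseline",
    "metrics", "peak_time_ms", "ms", "time of the peak after stimulus onset",
    "metrics", "baseline_sd", "%dR/R", "SD of the 10-frame pre-stimulus baseline",
    "metrics", "included", "", "peak_amp >= 2 x baseline_sd",
    "metrics", "hyp_amp", "%dR/R", "magnitude of the post-peak below-baseline excursion (to 300 ms)",
    "metrics", "hyp_time_ms", "ms", "time of the hyperpolarisation minimum",
    "metrics", "decay50_ms", "ms", "time to decay to half the peak (linear interpolation)",
    "traces", "drr_pct", "%dR/R", "region-averaged ratiometric voltage signal",
    "traces", "n_pixels", "px", "valid pixels averaged",
    "adaptation", "ratio", "", "second / first evoked depolarisation amplitude",
    "adaptation", "interstim_ms", "ms", "inter-stimulus interval",
    "movement", "max_changed_pct", "%", "maximum changed-pixel fraction in the analysis window",
    "movement", "label", "", "quiet or movement (0.5% separator, strict)"
  )
}
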