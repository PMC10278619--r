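#' Check video/biosignal synchronization
#'
#' Verifies that the recorded trigger edges are consistent with the video:
#' edge count against frame count (a mismatch beyond 1 is a hard error),
#' edge-interval regularity (intervals must stay within 2 samples of
#' `fs/fps`; any deviation at all is reported as a warning), and overall
#' recording-length consistency.
#'
#' @param biosignal Tibble with columns `time_s`, `ecg`, `trigger`.
#' @param n_frames Number of video frames.
#' @param fs Biosignal sampling rate in Hz.
#' @param fps Nominal frame rate in Hz.
#' @return Tibble report with columns `check`, `status`
#'   (`"ok"`/`"warning"`), `detail`; rows only for findings (empty when
#'   fully consistent). Hard inconsistencies raise a synchronization
#'   error.
#' @export
validate_sync <- function(biosignal, n_frames, fs = 1000, fps = 25) {
  edges <- detect_trigger_edges(biosignal, fs = fs, nominal_fps = fps)
  findings <- list()
  if (abs(length(edges) - n_frames) > 1) {
    abort(sprintf("synchronization error: %d trigger edges vs %d frames.",
                  length(edges), n_frames),
          class = "veinpulse_sync_error")
  }
  if (length(edges) != n_frames) {
    findings[[length(findings) + 1]] <- tibble(
      check = "edge_count", status = "warning",
      detail = sprintf("%d edges vs %d frames", length(edges), n_frames))
  }
  spf <- fs / fps
  dev <- abs(diff(edges) - spf)
  if (any(dev > 2)) {
    abort(sprintf("synchronization error: trigger interval deviates %g samples from fs/fps = %g.",
                  max(dev), spf), class = "veinpulse_sync_error")
  }
  if (any(dev > 0)) {
    findings[[length(findings) + 1]] <- tibble(
      check = "edge_regularity", status = "warning",
      detail = sprintf("max interval deviation %g sample(s)", max(dev)))
  }
  bio_span <- tail(biosignal$time_s, 1) - biosignal$time_s[1]
  if (abs(bio_span - n_frames / fps) > 2 / fps) {
    findings[[length(findings) + 1]] <- tibble(
      check = "recording_length", status = "warning",
      detail = sprintf("biosignal spans %.2f s vs %.2f s of video",
                       bio_span, n_frames / fps))
  }
  if (length(findings)) dplyr::bind_rows(findings) else
    tibble(check = character(0), status = character(0), detail = character(0))
}

# Shared analysis core: VP table + R-waves + timeline -> vp_analysis.
analyze_vp_tables <- function(vp, r_waves, timeline, fps, window_ms = 220,
                              max_interp_per_cycle = 0,
                              manual_excluded = integer(0),
                              extras = list()) {
  signal <- process_vp_signal(vp, r_waves, fps)
  cycles <- detect_vein_collapse(signal$i_ppg, r_waves, timeline, window_ms)
  cycles <- select_valid_cycles(cycles, timeline,
                                interp_frames = vp$frame[!vp$valid],
                                max_interp_per_cycle = max_interp_per_cycle,
                                manual_excluded = manual_excluded,
                                window_ms = window_ms)
  structure(c(list(cycles = cycles, signal = signal, r_waves = r_waves,
                   timeline = timeline, fps = fps, window_ms = window_ms,
                   window_n = attr(signal, "window_n")),
              extras),
            class = "vp_analysis")
}

#' Analyse a simulated recording in memory
#'
#' Runs the full measurement chain on a [simulate_subject()] bundle:
#' R-wave and trigger detection, frame-timeline construction, then either
#' the rendered video route (align, distorted-frame detection, ROI
#' extraction) or the analytic signal-level trace, followed by
#' interpolation, photoplethysmographic normalization, collapse detection
#' and cycle selection.
#'
#' @param sim A `vp_simulation`.
#' @param use_video Use the rendered frames (if present) instead of the
#'   analytic trace.
#' @param window_ms Collapse search window in ms.
#' @param alpha GESD significance level for distorted-frame detection.
#' @param manual_bad_frames,manual_excluded_cycles Manual overrides.
#' @return A `vp_analysis` object; see [tidy.vp_analysis()].
#' @export
analyze_simulation <- function(sim, use_video = !is.null(sim$video),
                               window_ms = 220, alpha = 0.05,
                               manual_bad_frames = integer(0),
                               manual_excluded_cycles = integer(0)) {
  stopifnot(inherits(sim, "vp_simulation"))
  r_waves <- detect_r_waves(sim$biosignal, fs = sim$fs)
  edges <- detect_trigger_edges(sim$biosignal, fs = sim$fs, nominal_fps = sim$fps)
  extras <- list()
  if (use_video) {
    al <- align_frames(sim$video)
    dd <- detect_distorted_frames(al$video, alpha = alpha,
                                  manual_bad = manual_bad_frames)
    vp <- extract_vp_signal(dd$video, sim$roi_mask)
    n_frames <- dd$video$n_frames
    extras <- list(distortion = dd$report, shifts = al$shifts)
  } else {
    vp <- tibble(frame = sim$trace$frame, i_vp = sim$trace$i_vp,
                 valid = rep(TRUE, nrow(sim$trace)))
    if (length(manual_bad_frames)) vp$valid[manual_bad_frames] <- FALSE
    n_frames <- nrow(vp)
  }
  timeline <- build_frame_timeline(edges, n_frames, fs = sim$fs, fps = sim$fps)
  analyze_vp_tables(vp, r_waves, timeline, fps = sim$fps,
                    window_ms = window_ms,
                    manual_excluded = manual_excluded_cycles,
                    extras = extras)
}

#' Run the full pipeline on recorded files
#'
#' End-to-end orchestration: reads the video (multi-page TIFF), biosignal
#' CSV and ROI mask; validates synchronization; aligns frames; detects
#' distorted frames; extracts, interpolates and normalises the VP signal;
#' detects per-cycle vein collapse; selects valid cycles; and writes all
#' intermediate tables, a JSON summary and a provenance record under
#' `out_dir`.
#'
#' @param video_path,biosignal_path,roi_path Input files.
#' @param out_dir Output directory (created).
#' @param fs,fps Sampling and frame rates in Hz.
#' @param window_ms Collapse search window in ms.
#' @param alpha GESD significance level.
#' @param manual_bad_frames,manual_excluded_cycles Manual overrides.
#' @return A `vp_analysis` object, invisibly.
#' @export
run_pipeline <- function(video_path, biosignal_path, roi_path, out_dir,
                         fs = 1000, fps = 25, window_ms = 220, alpha = 0.05,
                         manual_bad_frames = integer(0),
                         manual_excluded_cycles = integer(0)) {
  for (p in c(video_path, biosignal_path, roi_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p),
            class = "veinpulse_input_error")
    }
  }
  video <- read_video_tiff(video_path)
  biosignal <- read_biosignal(biosignal_path)
  roi <- read_roi_mask(roi_path)
  sync <- validate_sync(biosignal, video$n_frames, fs = fs, fps = fps)

  sim_like <- structure(list(biosignal = biosignal, fs = fs, fps = fps,
                             video = video, roi_mask = roi, trace = NULL),
                        class = "vp_simulation")
  res <- analyze_simulation(sim_like, use_video = TRUE, window_ms = window_ms,
                            alpha = alpha,
                            manual_bad_frames = manual_bad_frames,
                            manual_excluded_cycles = manual_excluded_cycles)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$r_waves, file.path(out_dir, "r_waves.csv"))
  readr::write_csv(res$timeline, file.path(out_dir, "timeline.csv"))
  readr::write_csv(res$distortion, file.path(out_dir, "distortion.csv"))
  readr::write_csv(as_tibble(res$signal), file.path(out_dir, "vp_signal.csv"))
  readr::write_csv(res$cycles, file.path(out_dir, "cycles.csv"))
  if (nrow(sync)) readr::write_csv(sync, file.path(out_dir, "sync_report.csv"))
  jsonlite::write_json(glance(res), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  params <- list(fs = fs, fps = fps, window_ms = window_ms, alpha = alpha,
                 window_n = res$window_n,
                 n_flagged_frames = sum(res$distortion$flagged),
                 manual_bad_frames = manual_bad_frames,
                 manual_excluded_cycles = manual_excluded_cycles)
  prov <- list(
    package = "veinpulse",
    version = as.character(utils::packageVersion("veinpulse")),
    inputs = list(video = video_path, biosignal = biosignal_path,
                  roi = roi_path),
    params = params,
    config_hash = rlang::hash(params))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' @export
print.vp_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<vp_analysis> %d cardiac cycles (%d valid)\n",
    "  median T_vc: %.1f ms (%.1f%% of cycle)\n",
    "  mean RR: %.3f s, SDRR: %.1f ms, MA window: %d frames\n"),
    g$n_cycles, g$n_valid, g$tvc_median_ms, g$tvc_median_pct,
    g$mean_rr_s, g$sdrr_s * 1000, x$window_n))
  invisible(x)
}

#' Tidy and glance methods for a pipeline result
#'
#' `tidy()` returns the per-cycle table (one row per cardiac cycle);
#' `glance()` a one-row summary of the recording.
#'
#' @param x A `vp_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vp_analysis <- function(x, ...) x$cycles

#' @rdname tidy.vp_analysis
#' @export
glance.vp_analysis <- function(x, ...) {
  v <- dplyr::filter(x$cycles, .data$valid)
  rr <- diff(x$r_waves$time_s)
  tibble(
    n_cycles = nrow(x$cycles), n_valid = nrow(v),
    tvc_median_ms = median(v$tvc_ms), tvc_min_ms = min(v$tvc_ms),
    tvc_max_ms = max(v$tvc_ms), tvc_median_pct = median(v$tvc_rel_pct),
    mean_rr_s = mean(rr), sdrr_s = compute_sdrr(rr),
    window_n = x$window_n)
}
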