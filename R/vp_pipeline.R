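#' Interpolate the VP signal over distorted frames
#'
#' Replaces the VP-signal values at distorted frames by 1-D cubic
#' interpolation through the good samples ([stats::spline()], `"fmm"`
#' boundary cubics, so an exact cubic trend is reproduced exactly). Good
#' samples are never altered; distorted frames before the first or after
#' the last good frame take the nearest good value.
#'
#' @param i_vp Numeric VP signal, one value per frame.
#' @param bad Integer indices of distorted frames.
#' @return Numeric vector, same length, with `bad` positions replaced.
#' @export
interpolate_distorted <- function(i_vp, bad = integer(0)) {
  x <- as.numeric(i_vp)
  bad <- sort(unique(as.integer(bad)))
  if (!length(bad)) return(x)
  if (any(bad < 1 | bad > length(x))) {
    abort("bad frame indices out of range.", class = "veinpulse_input_error")
  }
  good <- setdiff(seq_along(x), bad)
  if (length(good) < 4) {
    abort("need at least 4 good frames to interpolate.",
          class = "veinpulse_input_error")
  }
  inner <- bad[bad > min(good) & bad < max(good)]
  if (length(inner)) {
    x[inner] <- spline(good, x[good], xout = inner, method = "fmm")$y
  }
  x[bad[bad < min(good)]] <- x[min(good)]
  x[bad[bad > max(good)]] <- x[max(good)]
  x
}

#' Moving-average window length for the VP signal
#'
#' The low-frequency component is estimated with a moving average whose
#' window spans 1.5 mean cardiac cycles: `round(1.5 * mean_rr * fps)`,
#' incremented to the next odd integer so the filter is centred. At a mean
#' R-R of 0.93 s and 25 fps this gives N = 35 frames.
#'
#' @param mean_rr_s Mean R-R interval in seconds.
#' @param fps Frame rate in Hz.
#' @return Odd integer window length in frames.
#' @export
#' @examples
#' moving_average_window(0.93, 25)
moving_average_window <- function(mean_rr_s, fps) {
  stopifnot(mean_rr_s > 0, fps > 0)
  n <- as.integer(round(1.5 * mean_rr_s * fps))
  if (n %% 2L == 0L) n <- n + 1L
  max(n, 1L)
}

#' Low-frequency component of the VP signal
#'
#' Centred moving average of the VP signal with the window of
#' [moving_average_window()] (1.5 mean cardiac cycles, estimated from the
#' detected R-waves), reflect boundary handling.
#'
#' @param i_vp Numeric VP signal.
#' @param r_waves Tibble from [detect_r_waves()] (needs >= 2 rows to
#'   estimate the mean R-R interval).
#' @param fps Frame rate in Hz.
#' @return A list with `i_avg` (numeric) and `window_n` (odd integer).
#' @export
compute_moving_average <- function(i_vp, r_waves, fps = 25) {
  if (nrow(r_waves) < 2) {
    abort("need at least 2 R-waves to estimate the mean cardiac cycle.",
          class = "veinpulse_input_error")
  }
  mean_rr <- mean(diff(r_waves$time_s))
  n <- moving_average_window(mean_rr, fps)
  if (n >= length(i_vp)) {
    abort(sprintf(
      "moving-average window (%d frames) is not shorter than the recording (%d frames); a longer recording is required.",
      n, length(i_vp)), class = "veinpulse_input_error")
  }
  list(i_avg = moving_average_filter(as.numeric(i_vp), n), window_n = n)
}

#' Photoplethysmographic transform of the VP signal
#'
#' Normalises the VP signal by its low-frequency component,
#' `i_vprel = i_vp / i_avg` (fluctuating around 1, common illumination
#' gain cancelled), and expresses it as a photoplethysmographic signal in
#' percent, `i_ppg = 100 * (1 - i_vprel)`, in which each per-cycle
#' minimum marks the minimum vein volume, i.e. vein collapse.
#'
#' @param i_vp Raw VP signal.
#' @param i_avg Its moving-average component (must be positive).
#' @return A list with `i_vprel` and `i_ppg`.
#' @export
ppg_transform <- function(i_vp, i_avg) {
  i_vp <- as.numeric(i_vp); i_avg <- as.numeric(i_avg)
  stopifnot(length(i_vp) == length(i_avg))
  nonpos <- which(i_avg <= 0)
  if (length(nonpos)) {
    abort(sprintf("non-positive moving average at frame %d.", nonpos[1]),
          class = "veinpulse_numeric_error")
  }
  i_vprel <- i_vp / i_avg
  list(i_vprel = i_vprel, i_ppg = 100 * (1 - i_vprel))
}

#' Assemble the full VP signal table
#'
#' Convenience wrapper: interpolates distorted frames, computes the
#' moving-average component and the photoplethysmographic transform, and
#' returns everything as one per-frame tibble.
#'
#' @param vp Tibble from [extract_vp_signal()] (columns `frame`, `i_vp`,
#'   `valid`).
#' @param r_waves Tibble from [detect_r_waves()].
#' @param fps Frame rate in Hz.
#' @return Tibble with columns `frame`, `time_s`, `i_vp`, `i_avg`,
#'   `i_vprel`, `i_ppg`, `valid`; attribute `window_n`.
#' @export
process_vp_signal <- function(vp, r_waves, fps = 25) {
  bad <- vp$frame[!vp$valid]
  i_vp <- interpolate_distorted(vp$i_vp, bad)
  ma <- compute_moving_average(i_vp, r_waves, fps)
  pg <- ppg_transform(i_vp, ma$i_avg)
  out <- tibble(frame = vp$frame, time_s = (vp$frame - 1) / fps,
                i_vp = i_vp, i_avg = ma$i_avg,
                i_vprel = pg$i_vprel, i_ppg = pg$i_ppg, valid = vp$valid)
  attr(out, "window_n") <- ma$window_n
  class(out) <- c("vp_signal", class(out))
  out
}

#' Detect vein collapse in each cardiac cycle
#'
#' For each R-wave at time `t_R`, searches the frames whose start times
#' fall in `(t_R, t_R + window_ms/1000]` for the minimum of the
#' photoplethysmographic signal; the minimum is refined to sub-frame
#' precision by a parabolic fit through it and its two neighbouring
#' frames. The time from the R-wave to that minimum is the time to vein
#' collapse, `tvc_ms`. Cycles whose minimum sits on the first or last
#' frame of the window are flagged `boundary_minimum`; the last R-wave
#' (no following R-wave, so no cycle length) and windows running past the
#' recording end are dropped.
#'
#' @param i_ppg Photoplethysmographic signal (percent), one value per
#'   frame.
#' @param r_waves Tibble from [detect_r_waves()].
#' @param timeline Tibble from [build_frame_timeline()].
#' @param window_ms Search window after the R-wave in milliseconds (220 in
#'   the study, from the literature on collapse timing).
#' @return Tibble with one row per cycle: `cycle`, `r_time_s`,
#'   `next_r_time_s`, `rr_s`, `collapse_time_s`, `tvc_ms`, `tvc_rel_pct`
#'   (`100 * tvc_ms / (1000 * rr_s)`), `n_window_frames`, `valid`,
#'   `exclusion_reason`.
#' @export
detect_vein_collapse <- function(i_ppg, r_waves, timeline, window_ms = 220) {
  i_ppg <- as.numeric(i_ppg)
  ft <- timeline$time_s
  fs_frame <- if (nrow(timeline) > 1) median(diff(ft)) else NA_real_
  n_r <- nrow(r_waves)
  if (n_r < 2) {
    abort("need at least 2 R-waves to form a cardiac cycle.",
          class = "veinpulse_input_error")
  }
  rows <- list()
  for (i in seq_len(n_r - 1)) {
    t_r <- r_waves$time_s[i]
    t_next <- r_waves$time_s[i + 1]
    if (t_r + window_ms / 1000 > tail(ft, 1)) {
      inform(sprintf("cycle %d: search window runs past the recording; dropped.", i))
      next
    }
    in_win <- which(ft > t_r & ft <= t_r + window_ms / 1000)
    if (!length(in_win)) next
    vals <- i_ppg[in_win]
    k <- in_win[which.min(vals)]
    boundary <- k == in_win[1] || k == tail(in_win, 1)
    t_c <- ft[k]
    # sub-frame parabolic refinement through the minimum and its neighbours
    if (k > 1 && k < length(i_ppg)) {
      y0 <- i_ppg[k - 1]; y1 <- i_ppg[k]; y2 <- i_ppg[k + 1]
      den <- y0 - 2 * y1 + y2
      if (den > 0) {
        delta <- max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
        t_c <- t_c + delta * fs_frame
      }
    }
    tvc <- (t_c - t_r) * 1000
    rr <- t_next - t_r
    rows[[length(rows) + 1]] <- tibble(
      cycle = i, r_time_s = t_r, next_r_time_s = t_next, rr_s = rr,
      collapse_time_s = t_c, tvc_ms = tvc,
      tvc_rel_pct = 100 * tvc / (1000 * rr),
      n_window_frames = length(in_win),
      valid = !boundary,
      exclusion_reason = if (boundary) "boundary_minimum" else "none"
    )
  }
  if (!length(rows)) {
    abort("no cardiac cycle has a complete search window in the recording.",
          class = "veinpulse_input_error")
  }
  dplyr::bind_rows(rows)
}

#' Select valid cardiac cycles
#'
#' Replaces the study's manual exclusion of distorted cycles with
#' documented automatic rules: a cycle is invalidated when the number of
#' interpolated (distorted) frames inside its search window exceeds
#' `max_interp_per_cycle`, when its minimum sat on the window boundary
#' (`boundary_minimum`, set upstream), or when listed in
#' `manual_excluded`.
#'
#' @param cycles Tibble from [detect_vein_collapse()].
#' @param timeline Tibble from [build_frame_timeline()].
#' @param interp_frames Frame indices that were interpolated.
#' @param max_interp_per_cycle Tolerated interpolated frames per search
#'   window.
#' @param manual_excluded Cycle numbers to exclude by hand.
#' @param window_ms Search window, must match the detection call.
#' @return `cycles` with `valid` and `exclusion_reason` updated.
#' @export
select_valid_cycles <- function(cycles, timeline, interp_frames = integer(0),
                                max_interp_per_cycle = 0,
                                manual_excluded = integer(0),
                                window_ms = 220) {
  ft <- timeline$time_s
  interp_t <- ft[timeline$frame %in% interp_frames]
  out <- cycles
  for (i in seq_len(nrow(out))) {
    if (out$exclusion_reason[i] != "none") next
    n_interp <- sum(interp_t > out$r_time_s[i] &
                      interp_t <= out$r_time_s[i] + window_ms / 1000)
    if (n_interp > max_interp_per_cycle) {
      out$valid[i] <- FALSE
      out$exclusion_reason[i] <- "interpolated_overlap"
    }
  }
  manual <- out$cycle %in% manual_excluded
  out$valid[manual] <- FALSE
  out$exclusion_reason[manual] <- "manual"
  out
}
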