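#' Detect ECG R-waves
#'
#' The study's adaptive R-wave detector: the raw ECG is median filtered
#' (size 10 samples at 1000 Hz), smoothed with a Gaussian (sigma = 12
#' samples), and baseline-corrected by subtracting a Gaussian low-pass
#' (sigma = 200 samples); robust local maxima are then picked with
#' parameters computed on the filtered signal — height threshold `max/4`,
#' prominence `(max - min)/2`, and a minimum separation of 0.545 s (a 110
#' bpm ceiling). All thresholds are adaptive, so rescaling the ECG by any
#' positive constant leaves the detections unchanged. Filter sizes are
#' stated in samples at 1000 Hz and scale proportionally at other rates.
#'
#' @param biosignal Data frame with an `ecg` column (and optionally
#'   `time_s`), one row per sample.
#' @param fs Sampling rate in Hz.
#' @return Tibble with columns `sample_index` (1-based) and `time_s`
#'   (`(sample_index - 1)/fs`), one row per detected R-wave, increasing.
#' @export
#' @examples
#' sim <- generate_ecg(sim_config(duration = 10, seed = 7))
#' detect_r_waves(sim$signal, fs = 1000)
detect_r_waves <- function(biosignal, fs = 1000) {
  ecg <- as.numeric(biosignal$ecg %||% abort("`biosignal` needs an `ecg` column.",
                                             class = "veinpulse_input_error"))
  min_dist_s <- 0.545   # the stated minimal peak distance (110 bpm ceiling)
  if (length(ecg) < 2 * min_dist_s * fs) {
    abort("ECG record too short for R-wave detection.",
          class = "veinpulse_input_error")
  }
  scale <- fs / 1000
  f <- median_filter(ecg, max(2L, round(10 * scale)))
  f <- gaussian_filter(f, 12 * scale)
  f <- f - gaussian_filter(f, 200 * scale)
  mx <- max(f); mn <- min(f)
  if (mx == mn) {
    return(tibble(sample_index = integer(0), time_s = numeric(0)))
  }
  peaks <- find_peaks(f, threshold = mx / 4, prominence = (mx - mn) / 2,
                      min_distance = min_dist_s * fs)
  tibble(sample_index = peaks, time_s = (peaks - 1) / fs)
}

#' Detect camera trigger rising edges
#'
#' Applies the local-maxima detector to the first-order difference of the
#' trigger channel: peaks above half the square-wave magnitude
#' (`(max - min)/2` of the trigger), with a minimum separation of
#' 0.6 x the nominal frame period and no smoothing or prominence
#' criterion. The signal minimum is prepended before differencing so a
#' recording that starts in the high state still registers its first edge.
#'
#' @param biosignal Data frame with a `trigger` column.
#' @param fs Sampling rate in Hz.
#' @param nominal_fps Nominal frame rate in Hz (sets the minimum edge
#'   separation `0.6 * fs/nominal_fps` samples).
#' @return Integer vector of 1-based sample indices of rising edges.
#' @export
detect_trigger_edges <- function(biosignal, fs = 1000, nominal_fps = 25) {
  trig <- as.numeric(biosignal$trigger %||%
                       abort("`biosignal` needs a `trigger` column.",
                             class = "veinpulse_input_error"))
  d <- diff(c(min(trig), trig))
  magnitude <- max(trig) - min(trig)
  edges <- find_peaks(d, threshold = magnitude / 2,
                      min_distance = 0.6 * fs / nominal_fps, boundary = TRUE)
  if (length(edges) < 2) {
    abort("fewer than 2 trigger edges found: cannot synchronize.",
          class = "veinpulse_sync_error")
  }
  as.integer(edges)
}

#' Build the frame timeline
#'
#' Maps each video frame to the biosignal sample of its trigger rising
#' edge. If more edges than frames were recorded, the first `n_frames`
#' edges are used (with a warning); fewer edges than frames is a
#' synchronization error.
#'
#' @param edges Integer sample indices of trigger rising edges (1-based).
#' @param n_frames Number of frames actually recorded.
#' @param fs Biosignal sampling rate in Hz.
#' @param fps Video frame rate in Hz.
#' @return Tibble with columns `frame` (1-based), `sample_index` and
#'   `time_s`; attribute `exposure_samples = round(fs/fps)`.
#' @export
build_frame_timeline <- function(edges, n_frames, fs = 1000, fps = 25) {
  if (length(edges) < n_frames) {
    abort(sprintf("synchronization error: %d trigger edges for %d frames.",
                  length(edges), n_frames),
          class = "veinpulse_sync_error")
  }
  if (length(edges) > n_frames) {
    warn(sprintf("%d trigger edges for %d frames; using the first %d.",
                 length(edges), n_frames, n_frames))
    edges <- edges[seq_len(n_frames)]
  }
  tl <- tibble(frame = seq_len(n_frames),
               sample_index = as.integer(edges),
               time_s = (as.integer(edges) - 1) / fs)
  attr(tl, "exposure_samples") <- exposure_samples(fs, fps)
  attr(tl, "fs") <- fs
  attr(tl, "fps") <- fps
  tl
}

#' Map R-waves to fractional frame positions
#'
#' Places each R-wave on the frame axis by linear interpolation between the
#' surrounding frame-start samples, giving sub-frame positions for timing
#' arithmetic. R-waves before the first or after the last frame start are
#' dropped with a message.
#'
#' @param r_waves Tibble from [detect_r_waves()].
#' @param timeline Tibble from [build_frame_timeline()].
#' @return Tibble with columns `sample_index`, `time_s` and `frame_pos`
#'   (fractional, 1-based).
#' @export
r_wave_to_frame <- function(r_waves, timeline) {
  s <- r_waves$sample_index
  inside <- s >= timeline$sample_index[1] & s <= tail(timeline$sample_index, 1)
  if (any(!inside)) {
    inform(sprintf("%d R-wave(s) outside the frame timeline dropped.",
                   sum(!inside)))
  }
  s <- s[inside]
  pos <- approx(x = timeline$sample_index, y = timeline$frame, xout = s)$y
  tibble(sample_index = s, time_s = r_waves$time_s[inside], frame_pos = pos)
}
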