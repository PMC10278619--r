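#' Generate a synthetic ECG with known R-wave times
#'
#' Builds a quasi-periodic ECG as a sum of Gaussian deflections per beat
#' (P wave, a dominant ~25 ms wide QRS, T wave) on top of slow baseline
#' wander and additive white noise. R-R intervals are drawn with mean
#' `60/hr_mean` s and standard deviation `hr_sd * 60 / hr_mean^2` s (the
#' first-order propagation of the bpm dispersion), truncated from below at
#' the configured `rr_floor_s`. The QRS is wide enough that the study's
#' size-10 median prefilter attenuates but cannot remove it.
#'
#' @param config A [sim_config()].
#' @return A list with `signal`, a tibble with columns `time_s` and `ecg`,
#'   and `truth`, a ground-truth list carrying `r_wave_times` (s),
#'   `mean_rr` (s) and the per-cycle `collapse_delay_ms`.
#' @export
#' @examples
#' sim <- generate_ecg(sim_config(duration = 10, seed = 42))
#' head(sim$truth$r_wave_times)
generate_ecg <- function(config) {
  validate_sim_config(config)
  with_sim_rng(config$seed, {
    fs <- config$fs_bio
    n <- as.integer(round(config$duration * fs))
    t <- (seq_len(n) - 1) / fs
    mean_rr <- 60 / config$hr_mean
    sd_rr <- config$hr_sd * 60 / config$hr_mean^2
    rr_floor <- config$rr_floor_s %||% min_rr_interval(110)

    t0 <- 0.35
    r_times <- t0
    while (tail(r_times, 1) < config$duration) {
      rr <- max(rr_floor, rnorm(1, mean_rr, sd_rr))
      r_times <- c(r_times, tail(r_times, 1) + rr)
    }
    r_times <- r_times[r_times < config$duration - 0.05]
    rr <- diff(r_times)

    ecg <- numeric(n)
    bump <- function(centre, amp, sigma) amp * exp(-0.5 * ((t - centre) / sigma)^2)
    for (i in seq_along(r_times)) {
      tr <- r_times[i]
      cyc <- if (i <= length(rr)) rr[i] else mean_rr
      ecg <- ecg + bump(tr, 1.0, 0.012)            # QRS, FWHM ~ 28 ms
      ecg <- ecg + bump(tr - 0.18 * cyc, 0.10, 0.025) # P
      ecg <- ecg + bump(tr + 0.30 * cyc, 0.20, 0.050) # T
    }
    ecg <- ecg +
      0.15 * sin(2 * pi * 0.23 * t + runif(1, 0, 2 * pi)) +
      0.08 * sin(2 * pi * 0.09 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, config$ecg_noise_sd)

    truth <- new_vp_truth(config, r_times)
    list(signal = tibble(time_s = t, ecg = ecg), truth = truth)
  })
}

new_vp_truth <- function(config, r_times) {
  structure(list(
    r_wave_times = r_times,
    mean_rr = 60 / config$hr_mean,
    collapse_delay_ms = rep(config$collapse_delay_ms, length(r_times)),
    collapse_times = r_times + config$collapse_delay_ms / 1000,
    distorted_frame_indices = integer(0),
    roi_mask = NULL,
    illumination_profile = NULL,
    shifts = NULL
  ), class = "vp_truth")
}

#' Override the per-cycle collapse delays of a ground truth
#'
#' The generator defaults to one configured delay for every cycle; this
#' sets an explicit per-cycle delay vector (recycled to the number of
#' beats), e.g. to construct delays as a fixed fraction of each cycle
#' length.
#'
#' @param truth Ground truth from [generate_ecg()].
#' @param delays_ms Numeric delays in ms, in (0, 220], one per beat
#'   (recycled).
#' @return The updated truth.
#' @export
set_collapse_delays <- function(truth, delays_ms) {
  stopifnot(inherits(truth, "vp_truth"))
  d <- rep_len(as.numeric(delays_ms), length(truth$r_wave_times))
  if (any(d <= 0 | d > 220)) {
    abort("collapse delays must lie in (0, 220] ms.",
          class = "veinpulse_config_error")
  }
  truth$collapse_delay_ms <- d
  truth$collapse_times <- truth$r_wave_times + d / 1000
  truth
}

#' Generate the camera trigger square wave
#'
#' A square wave at the video frame rate: one rising edge per frame, edges
#' landing exactly on biosignal samples `1 + k * fs_bio/fps` (1-based), 50%
#' duty cycle. At 25 fps and 1000 Hz edges fall every 40 samples, so one
#' frame period spans 40 ECG samples.
#'
#' @param config A [sim_config()].
#' @return Numeric 0/1 vector of length `duration * fs_bio`.
#' @export
generate_trigger <- function(config) {
  validate_sim_config(config)
  spf <- config$fs_bio / config$fps
  if (abs(spf - round(spf)) > 1e-9) {
    abort("fs_bio/fps must be an integer number of samples per frame.",
          class = "veinpulse_config_error")
  }
  spf <- as.integer(round(spf))
  n <- as.integer(round(config$duration * config$fs_bio))
  k <- (seq_len(n) - 1) %% spf
  as.numeric(k < spf / 2)
}

# Normalised vein-volume waveform v(t) in [0, 1]: raised cosine per cardiac
# cycle, v = 0 (full collapse) exactly collapse_delay_ms (per cycle) after
# each R-wave, v = 1 half a cycle away. R-times are extended by the mean RR
# at both ends so frames before the first / after the last beat still get a
# phase (reusing the first/last cycle's delay).
vein_volume_waveform <- function(t, truth) {
  r <- truth$r_wave_times
  mrr <- truth$mean_rr
  delay_s <- rep_len(truth$collapse_delay_ms, length(r)) / 1000
  while (r[1] > min(t)) {
    r <- c(r[1] - mrr, r)
    delay_s <- c(delay_s[1], delay_s)
  }
  while (tail(r, 1) <= max(t)) {
    r <- c(r, tail(r, 1) + mrr)
    delay_s <- c(delay_s, tail(delay_s, 1))
  }
  cyc <- findInterval(t, r, rightmost.closed = FALSE)
  cyc <- pmin(pmax(cyc, 1L), length(r) - 1L)
  rr <- r[cyc + 1L] - r[cyc]
  phi <- (t - r[cyc]) / rr
  phi_c <- delay_s[cyc] / rr
  0.5 * (1 - cos(2 * pi * (phi - phi_c)))
}

# Slow (< 0.3 Hz) multiplicative illumination drift profile, peak |.| scaled
# to drift_amplitude. Deterministic under seed + 1.
illumination_gain <- function(config, t) {
  if (config$drift_amplitude == 0) return(rep(1, length(t)))
  with_sim_rng(config$seed + 1L, {
    g <- sin(2 * pi * 0.12 * t + runif(1, 0, 2 * pi)) +
      0.6 * sin(2 * pi * 0.27 * t + runif(1, 0, 2 * pi)) +
      0.4 * sin(2 * pi * 0.05 * t + runif(1, 0, 2 * pi))
    1 + config$drift_amplitude * g / max(abs(g))
  })
}

#' Generate the per-frame vein ROI intensity trace
#'
#' Signal-level emulation of the vein pulsation signal: the mean ROI
#' intensity of frame n is
#' `gain(n) * baseline * (1 - a * v(n)) + noise`, where `v(n)` is a raised
#' cosine per cardiac cycle that reaches its minimum (vein collapse, hence
#' ROI intensity maximum — the vein is a dark structure) exactly
#' `collapse_delay_ms` after each R-wave, `gain(n)` is slow multiplicative
#' illumination drift and the noise is white. Ground-truth collapse times
#' are `r_wave_times + collapse_delay_ms/1000`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_ecg()].
#' @param baseline Baseline ROI intensity on the [0, 1] scale.
#' @param noise Add the white-noise term? Set `FALSE` to obtain the
#'   noise-free analytic reference (used when noise is instead injected
#'   per pixel at the frame-rendering stage).
#' @return A list with `trace`, a tibble with columns `frame`, `time_s` and
#'   `i_vp`, and the updated `truth` (gains recorded in
#'   `illumination_profile`).
#' @export
generate_vp_trace <- function(config, truth, baseline = 0.5, noise = TRUE) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "vp_truth"), length(truth$r_wave_times) > 0)
  n_frames <- as.integer(floor(config$duration * config$fps))
  t <- (seq_len(n_frames) - 1) / config$fps
  v <- vein_volume_waveform(t, truth)
  gain <- illumination_gain(config, t)
  sd_eps <- if (noise) config$noise_sd else 0
  eps <- with_sim_rng(config$seed + 3L, rnorm(n_frames, 0, sd_eps))
  i_vp <- gain * baseline * (1 - config$pulsation_amplitude * v) + eps
  truth$illumination_profile <- gain
  list(trace = tibble(frame = seq_len(n_frames), time_s = t, i_vp = i_vp),
       truth = truth)
}
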