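#' Configuration for the synthetic acquisition generator
#'
#' Describes one simulated recording session of the emulated acquisition
#' system: an ECG and a camera trigger sampled at `fs_bio`, and a fundus
#' video at `fps` whose vein region dips in diameter (collapses) at a known
#' delay after each R-wave. Defaults reproduce the study conditions: 12 s
#' recordings (study range 10-15 s), 1000 Hz biosignals, 25 fps video,
#' resting heart rate 64 +/- 3 bpm, a 120 ms collapse delay (the middle of
#' the observed 60-220 ms range), ~4% photoplethysmographic modulation,
#' slow (< 0.3 Hz) multiplicative illumination drift and additive noise at
#' 10% of the modulation amplitude (the ROI mean averages per-pixel camera
#' noise down by orders of magnitude; pass ~0.01 for per-pixel noise when
#' rendering video frames).
#'
#' @param duration Recording length in seconds.
#' @param fs_bio Biosignal sampling rate in Hz; must be a positive multiple
#'   of `fps` so every frame starts on an integer biosignal sample.
#' @param fps Video frame rate in Hz.
#' @param hr_mean,hr_sd Heart rate mean and beat-to-beat standard deviation
#'   in bpm. R-R intervals are drawn with mean `60/hr_mean` and truncated
#'   from below at `rr_floor_s`.
#' @param rr_floor_s Minimum R-R interval in seconds. The default 0.55 s
#'   keeps every simulated beat above the detector's 0.545 s refractory
#'   with a guard band wider than the detector's peak-time jitter at
#'   1000 Hz, so simulated beats are always resolvable (and satisfies the
#'   physiological 110 bpm ceiling, 60/110 = 0.545 s).
#' @param collapse_delay_ms True R-wave to vein-collapse delay in
#'   milliseconds, in (0, 220].
#' @param pulsation_amplitude Peak modulation of the vein ROI intensity as a
#'   fraction of its baseline, in [0, 1).
#' @param drift_amplitude Peak multiplicative illumination drift, in [0, 1).
#' @param noise_sd Additive frame noise standard deviation (intensity units
#'   on the [0, 1] scale).
#' @param ecg_noise_sd Additive ECG noise standard deviation as a fraction
#'   of the R amplitude (which is 1).
#' @param blink_count Number of near-black blink frames to inject.
#' @param frame_size Length-2 integer, frame height and width in pixels.
#' @param jitter_px Maximum per-frame translation (integer pixels) injected
#'   to exercise frame alignment; 0 disables.
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration = 12, fs_bio = 1000, fps = 25,
                       hr_mean = 64, hr_sd = 3, rr_floor_s = 0.55,
                       collapse_delay_ms = 120,
                       pulsation_amplitude = 0.04, drift_amplitude = 0.05,
                       noise_sd = 0.002, ecg_noise_sd = 0.02,
                       blink_count = 0, frame_size = c(128, 128),
                       jitter_px = 0, seed = 1) {
  cfg <- list(
    duration = duration, fs_bio = fs_bio, fps = fps,
    hr_mean = hr_mean, hr_sd = hr_sd, rr_floor_s = rr_floor_s,
    collapse_delay_ms = collapse_delay_ms,
    pulsation_amplitude = pulsation_amplitude,
    drift_amplitude = drift_amplitude, noise_sd = noise_sd,
    ecg_noise_sd = ecg_noise_sd, blink_count = blink_count,
    frame_size = as.integer(frame_size), jitter_px = jitter_px,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (duration <= 0 || fs_bio <= 0 || fps <= 0 || hr_mean <= 0) {
      abort("duration, fs_bio, fps and hr_mean must be positive.",
            class = "veinpulse_config_error")
    }
    if (abs(fs_bio / fps - round(fs_bio / fps)) > 1e-9) {
      abort("fs_bio must be an integer multiple of fps (sample-aligned frames).",
            class = "veinpulse_config_error")
    }
    if (duration < 2 / (hr_mean / 60)) {
      abort("duration too short: need at least two cardiac cycles.",
            class = "veinpulse_config_error")
    }
    if (rr_floor_s <= 0 || rr_floor_s > duration / 2) {
      abort("rr_floor_s must be positive and far shorter than the recording.",
            class = "veinpulse_config_error")
    }
    if (hr_sd < 0 || noise_sd < 0 || ecg_noise_sd < 0 || blink_count < 0) {
      abort("hr_sd, noise levels and blink_count must be non-negative.",
            class = "veinpulse_config_error")
    }
    if (pulsation_amplitude < 0 || pulsation_amplitude >= 1 ||
        drift_amplitude < 0 || drift_amplitude >= 1) {
      abort("pulsation_amplitude and drift_amplitude must lie in [0, 1).",
            class = "veinpulse_config_error")
    }
    if (collapse_delay_ms <= 0 || collapse_delay_ms > 220) {
      abort("collapse_delay_ms must lie in (0, 220].",
            class = "veinpulse_config_error")
    }
    if (length(frame_size) != 2 || any(frame_size < 1)) {
      abort("frame_size must be two positive integers.",
            class = "veinpulse_config_error")
    }
  })
  invisible(cfg)
}

# Evaluate `expr` with a private RNG stream so generators are deterministic
# under the config seed and leave the caller's RNG untouched.
with_sim_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
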