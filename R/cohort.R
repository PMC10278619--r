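#' Simulate and analyse a cohort of subjects
#'
#' Draws one recording per subject at the signal level (no frame
#' rendering), with per-subject heart rate drawn uniformly from
#' `hr_range` and the true collapse delay either drawn independently of
#' the heart rate from `delay_range_ms` (the null of the cycle-length
#' independence check) or, with `delay_fraction_of_rr` set, constructed
#' as a fixed fraction of the subject's mean cycle length (a positive
#' control). Each recording is analysed end to end and the valid cycles
#' pooled.
#'
#' @param n_subjects Number of subjects.
#' @param duration Recording length per subject in seconds.
#' @param hr_range Heart-rate range in bpm.
#' @param delay_range_ms Collapse-delay range in ms (independent draw).
#' @param delay_fraction_of_rr If non-`NULL`, each cycle's delay = this
#'   fraction of that cycle's R-R interval (capped at 220 ms) instead.
#' @param noise_sd Frame-noise standard deviation passed to the generator.
#' @param seed Integer seed.
#' @return A list with `cycles` (pooled valid per-cycle tibble with
#'   `subject_id`, `rr_s`, `tvc_ms`, `tvc_rel_pct`, `true_delay_ms`) and
#'   `subjects` (per-subject truth and summary).
#' @export
simulate_cohort <- function(n_subjects = 13, duration = 12,
                            hr_range = c(55, 90), delay_range_ms = c(60, 220),
                            delay_fraction_of_rr = NULL, noise_sd = 0.002,
                            seed = 1) {
  draws <- with_sim_rng(seed, {
    tibble(
      subject = seq_len(n_subjects),
      hr = runif(n_subjects, hr_range[1], hr_range[2]),
      delay = runif(n_subjects, delay_range_ms[1], delay_range_ms[2]))
  })
  if (!is.null(delay_fraction_of_rr)) {
    draws$delay <- pmin(220, delay_fraction_of_rr * 60 / draws$hr * 1000)
  }
  res <- purrr::pmap(draws, function(subject, hr, delay) {
    cfg <- sim_config(duration = duration, hr_mean = hr, hr_sd = 2,
                      collapse_delay_ms = delay, noise_sd = noise_sd,
                      seed = seed * 1000L + subject)
    sim <- simulate_subject(cfg, render_video = FALSE)
    if (!is.null(delay_fraction_of_rr)) {
      # per-cycle delays tied to each cycle's own length
      r <- sim$truth$r_wave_times
      rr <- diff(r)
      d <- pmin(220, delay_fraction_of_rr * c(rr, mean(rr)) * 1000)
      truth <- set_collapse_delays(sim$truth, d)
      vt <- generate_vp_trace(cfg, truth)
      sim$trace <- vt$trace
      sim$truth <- vt$truth
    }
    an <- suppressMessages(analyze_simulation(sim, use_video = FALSE))
    cyc <- dplyr::filter(tidy(an), .data$valid)
    dplyr::mutate(cyc, subject_id = sprintf("S%02d", subject),
                  true_delay_ms = delay)
  })
  cycles <- dplyr::bind_rows(res)
  subjects <- cycles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_valid = dplyr::n(),
                     tvc_ms = median(.data$tvc_ms),
                     mean_rr_s = mean(.data$rr_s),
                     true_delay_ms = .data$true_delay_ms[1])
  list(cycles = cycles, subjects = subjects)
}
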