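test_that("cubic interpolation of distorted frames", {
  x <- sin(seq(0, 4 * pi, length.out = 60))
  expect_identical(interpolate_distorted(x), x)              # no bad frames
  # exact on a cubic trend
  i <- 1:30
  y <- 2 + 0.5 * i - 0.1 * i^2 + 0.01 * i^3
  expect_equal(interpolate_distorted(y, 13), y, tolerance = 1e-10)
  # two adjacent bad frames on a cardiac-frequency sinusoid: error well
  # below the pulsation amplitude
  t <- (0:149) / 25
  s <- 0.5 + 0.01 * sin(2 * pi * 1.1 * t)
  est <- interpolate_distorted(s, c(70, 71))
  expect_lt(max(abs(est[70:71] - s[70:71])), 0.05 * 0.02)
  # idempotence
  once <- interpolate_distorted(s, c(70, 71))
  expect_identical(interpolate_distorted(once, c(70, 71)), once)
  # edge frames take the nearest good value
  e <- interpolate_distorted(s, c(1, 2, 150))
  expect_equal(e[1:2], rep(s[3], 2))
  expect_equal(e[150], s[149])
  expect_error(interpolate_distorted(1:5, 1:3), class = "veinpulse_input_error")
})

test_that("moving-average window length and behaviour", {
  expect_equal(moving_average_window(0.93, 25), 35L)   # 1.5 cycles at 25 fps
  expect_equal(moving_average_window(0.8, 25), 31L)    # 30 -> forced odd
  rw <- tibble::tibble(sample_index = 1L, time_s = seq(0, 9.3, by = 0.93))
  ma <- compute_moving_average(rep(2.5, 300), rw, 25)
  expect_equal(ma$window_n, 35L)
  expect_equal(ma$i_avg, rep(2.5, 300))                # constants preserved
  # cardiac-frequency sinusoid is strongly attenuated by a 1.5-cycle
  # window; the residual matches the Dirichlet-kernel closed form
  t <- (0:299) / 25
  s <- sin(2 * pi * t / 0.93)
  ma2 <- compute_moving_average(s, rw, 25)
  gain_cf <- abs(sin(pi * 35 / (25 * 0.93)) / (35 * sin(pi / (25 * 0.93))))
  expect_lt(max(abs(ma2$i_avg[50:250])), gain_cf * 1.05)
  expect_lt(gain_cf, 0.25)
  expect_error(compute_moving_average(rep(1, 20), rw, 25),
               class = "veinpulse_input_error")
})

test_that("PPG transform identities", {
  x <- rep(4, 50)
  pg <- ppg_transform(x, x)
  expect_equal(pg$i_vprel, rep(1, 50))
  expect_equal(pg$i_ppg, rep(0, 50))
  set.seed(5)
  v <- runif(50, 0.4, 0.6); a <- runif(50, 0.45, 0.55)
  expect_equal(ppg_transform(v * 7.3, a * 7.3), ppg_transform(v, a))
  expect_equal(ppg_transform(v, a)$i_ppg, 100 * (1 - v / a))
  expect_error(ppg_transform(v, a - 1), class = "veinpulse_numeric_error")
})

test_that("modulation depth survives the transform", {
  cfg <- sim_config(duration = 12, pulsation_amplitude = 0.04, noise_sd = 0,
                    drift_amplitude = 0, seed = 4)
  sim <- simulate_subject(cfg, render_video = FALSE)
  rw <- detect_r_waves(sim$biosignal, 1000)
  ma <- compute_moving_average(sim$trace$i_vp, rw, 25)
  pg <- ppg_transform(sim$trace$i_vp, ma$i_avg)
  swing <- max(pg$i_ppg[30:270]) - min(pg$i_ppg[30:270])
  # the 1.5-cycle moving average leaves a ~21% ripple of the modulation in
  # the normalised signal, so the swing overshoots the nominal 4% slightly
  expect_equal(swing, 4, tolerance = 0.3)              # percent units
})

test_that("collapse detection recovers a noiseless 120 ms delay per cycle", {
  cfg <- sim_config(duration = 12, collapse_delay_ms = 120, noise_sd = 0,
                    seed = 1)
  sim <- simulate_subject(cfg, render_video = FALSE)
  an <- suppressMessages(analyze_simulation(sim, use_video = FALSE))
  v <- dplyr::filter(tidy(an), valid)
  expect_gt(nrow(v), 5)
  expect_true(all(abs(v$tvc_ms - 120) <= 20))          # within half a frame
  # relative time identity holds exactly
  expect_equal(v$tvc_rel_pct * v$rr_s * 10, v$tvc_ms)
})

test_that("a monotone window pins the minimum to the first frame and flags it", {
  tl <- build_frame_timeline(seq(1L, by = 40L, length.out = 100), 100, 1000, 25)
  rw <- tibble::tibble(sample_index = c(1001L, 2001L), time_s = c(1.0, 2.0))
  i_ppg <- seq(0, 1, length.out = 100)                 # strictly increasing
  cyc <- detect_vein_collapse(i_ppg, rw, tl, window_ms = 220)
  expect_equal(cyc$exclusion_reason[1], "boundary_minimum")
  expect_lte(cyc$tvc_ms[1], 40 + 20)
})

test_that("cycle selection applies interpolation, boundary and manual rules", {
  cfg <- sim_config(duration = 12, collapse_delay_ms = 120, noise_sd = 0, seed = 2)
  sim <- simulate_subject(cfg, render_video = FALSE)
  an <- suppressMessages(analyze_simulation(sim, use_video = FALSE))
  cyc <- tidy(an)
  expect_true(all(cyc$valid | cyc$exclusion_reason != "none"))
  # an interpolated frame inside cycle 3's window invalidates it
  w3 <- cyc$r_time_s[3]
  frame_in_w3 <- which((an$timeline$time_s > w3) &
                         (an$timeline$time_s <= w3 + 0.22))[1]
  sel <- select_valid_cycles(cyc, an$timeline, interp_frames = frame_in_w3,
                             max_interp_per_cycle = 0)
  expect_false(sel$valid[3])
  expect_equal(sel$exclusion_reason[3], "interpolated_overlap")
  # manual exclusion wins
  sel2 <- select_valid_cycles(cyc, an$timeline, manual_excluded = 2L)
  expect_equal(sel2$exclusion_reason[2], "manual")
})

test_that("valid cycle count on a 12 s recording sits in the expected range", {
  cfg <- sim_config(duration = 12, hr_mean = 64, blink_count = 2,
                    noise_sd = 0.01, seed = 10)
  sim <- simulate_subject(cfg)
  an <- suppressMessages(analyze_simulation(sim))
  n_valid <- sum(tidy(an)$valid)
  expect_gte(n_valid, 5)
  expect_lte(n_valid, 11)
})
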