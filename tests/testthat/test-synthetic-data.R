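test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration = 1), class = "veinpulse_config_error")
  expect_error(sim_config(fs_bio = 990, fps = 25), class = "veinpulse_config_error")
  expect_error(sim_config(collapse_delay_ms = 250), class = "veinpulse_config_error")
  expect_error(sim_config(pulsation_amplitude = 1.2), class = "veinpulse_config_error")
  expect_error(generate_video(sim_config(frame_size = c(32, 32)),
                              generate_ecg(sim_config())$truth),
               class = "veinpulse_config_error")
})

test_that("zero heart-rate variability gives an exactly periodic beat train", {
  sim <- generate_ecg(sim_config(duration = 10, hr_mean = 60, hr_sd = 0))
  r <- sim$truth$r_wave_times
  expect_equal(diff(r), rep(1, length(r) - 1))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(duration = 6, blink_count = 2, noise_sd = 0.01,
                    jitter_px = 2, seed = 9)
  a <- simulate_subject(cfg)
  b <- simulate_subject(cfg)
  expect_identical(a$biosignal, b$biosignal)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$truth$distorted_frame_indices,
                   b$truth$distorted_frame_indices)
})

test_that("trigger square wave has one edge per frame at exact samples", {
  cfg <- sim_config(duration = 10, fps = 25, fs_bio = 1000)
  trig <- generate_trigger(cfg)
  rises <- which(diff(c(0, trig)) > 0.5)
  expect_equal(length(rises), 250)                    # duration x fps
  expect_equal(diff(rises), rep(40L, 249))            # fs/fps samples apart
  cfg10 <- sim_config(duration = 10, fps = 10, fs_bio = 1000)
  expect_equal(unique(diff(which(diff(c(0, generate_trigger(cfg10))) > 0.5))), 100L)
})

test_that("vp trace timing closure: collapse exactly at the configured delay", {
  cfg <- sim_config(duration = 10, collapse_delay_ms = 120, noise_sd = 0,
                    drift_amplitude = 0, seed = 2)
  sim <- generate_ecg(cfg)
  expect_equal(sim$truth$collapse_times - sim$truth$r_wave_times,
               rep(0.120, length(sim$truth$r_wave_times)))
  # the fine-sampled waveform attains its intensity maximum at the delay
  vt <- generate_vp_trace(cfg, sim$truth)
  t_fine <- seq(0, 10, by = 1e-3)
  v <- veinpulse:::vein_volume_waveform(t_fine, sim$truth)
  for (tr in sim$truth$r_wave_times[2:5]) {
    w <- which(t_fine > tr & t_fine <= tr + 0.22)
    expect_lt(abs(t_fine[w][which.min(v[w])] - tr - 0.120), 1.5e-3)
  }
})

test_that("vp trace degenerate cases", {
  cfg <- sim_config(duration = 8, pulsation_amplitude = 0, drift_amplitude = 0,
                    noise_sd = 0)
  truth <- generate_ecg(cfg)$truth
  tr <- generate_vp_trace(cfg, truth)$trace
  expect_equal(tr$i_vp, rep(0.5, nrow(tr)))           # constant at baseline
  # common gain cancels in the normalized signal
  cfg2 <- sim_config(duration = 8, noise_sd = 0)
  t2 <- generate_vp_trace(cfg2, generate_ecg(cfg2)$truth)$trace
  rw <- tibble::tibble(sample_index = 1L, time_s = truth$r_wave_times)
  ma1 <- compute_moving_average(t2$i_vp, rw, 25)
  ma2 <- compute_moving_average(2 * t2$i_vp, rw, 25)
  expect_equal(ppg_transform(t2$i_vp, ma1$i_avg)$i_vprel,
               ppg_transform(2 * t2$i_vp, ma2$i_avg)$i_vprel)
})

test_that("rendered video is static without modulation and matches its trace", {
  cfg0 <- sim_config(duration = 4, pulsation_amplitude = 0, drift_amplitude = 0,
                     noise_sd = 0, frame_size = c(64, 64))
  gv <- generate_video(cfg0, generate_ecg(cfg0)$truth)
  f1 <- gv$video$frames[, , 1]
  expect_true(all(apply(gv$video$frames, 3, function(f) identical(f, f1))))
  # render-then-measure round trip against the analytic trace
  cfg <- sim_config(duration = 6, noise_sd = 0, frame_size = c(64, 64), seed = 3)
  sim <- simulate_subject(cfg)
  vp <- extract_vp_signal(sim$video, sim$roi_mask)
  expect_gt(cor(vp$i_vp, sim$trace$i_vp), 0.99)
})

test_that("per-cycle delay override feeds through to the waveform", {
  cfg <- sim_config(duration = 8, noise_sd = 0, drift_amplitude = 0, seed = 5)
  truth <- generate_ecg(cfg)$truth
  delays <- seq(80, 200, length.out = length(truth$r_wave_times))
  truth2 <- set_collapse_delays(truth, delays)
  expect_equal(truth2$collapse_times, truth2$r_wave_times + delays / 1000)
  expect_error(set_collapse_delays(truth, 300), class = "veinpulse_config_error")
})

test_that("simulation round-trips through its on-disk formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(duration = 4, frame_size = c(64, 64), blink_count = 1,
                    noise_sd = 0.01, seed = 6)
  sim <- simulate_subject(cfg)
  write_simulation(sim, dir)
  bio <- read_biosignal(file.path(dir, "biosignal.csv"))
  expect_equal(attr(bio, "fs"), 1000)
  expect_equal(bio$ecg, sim$biosignal$ecg, tolerance = 1e-9)
  vid <- read_video_tiff(file.path(dir, "video.tiff"))
  expect_equal(vid$n_frames, sim$video$n_frames)
  expect_lt(max(abs(vid$frames - sim$video$frames)), 2e-4)  # 16-bit rounding
  roi <- read_roi_mask(file.path(dir, "roi.png"))
  expect_identical(roi, sim$roi_mask)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$distorted_frame_indices, sim$truth$distorted_frame_indices)
})
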