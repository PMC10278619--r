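make_textured_frame <- function(h, w, seed = 1) {
  set.seed(seed)
  y <- matrix(seq_len(h), h, w); x <- matrix(seq_len(w), h, w, byrow = TRUE)
  0.5 + 0.2 * sin(2 * pi * x / w * 3) * cos(2 * pi * y / h * 2) +
    matrix(rnorm(h * w, 0, 0.02), h, w)
}

test_that("phase correlation recovers known integer shifts exactly", {
  f <- make_textured_frame(64, 64)
  frames <- array(0, dim = c(64, 64, 4))
  frames[, , 1] <- f
  shifts <- rbind(c(0, 0), c(3, -2), c(-5, 4), c(2, 2))
  for (i in 2:4) frames[, , i] <- veinpulse:::shift_matrix(f, shifts[i, 1], shifts[i, 2])
  al <- align_frames(vp_video(frames))
  expect_equal(round(al$shifts$dy), shifts[, 1])
  expect_equal(round(al$shifts$dx), shifts[, 2])
  # round trip: residual shift after alignment is well under half a pixel,
  # so the realigned content matches the original closely away from edges
  expect_lt(max(abs(al$shifts$dy - shifts[, 1])), 0.5)
  expect_lt(max(abs(al$shifts$dx - shifts[, 2])), 0.5)
  for (i in 2:4) {
    interior <- al$video$frames[10:55, 10:55, i] - f[10:55, 10:55]
    expect_lt(max(abs(interior)), 0.05)
  }
})

test_that("alignment of a jitter-free video estimates zero shifts", {
  cfg <- sim_config(duration = 3, noise_sd = 0.005, frame_size = c(64, 64), seed = 8)
  sim <- simulate_subject(cfg)
  al <- align_frames(sim$video)
  expect_lt(max(abs(al$shifts$dy)), 0.5)
  expect_lt(max(abs(al$shifts$dx)), 0.5)
})

test_that("injected jitter is recovered from the generator's ground truth", {
  cfg <- sim_config(duration = 3, noise_sd = 0.005, frame_size = c(64, 64),
                    jitter_px = 3, seed = 12)
  sim <- simulate_subject(cfg)
  al <- align_frames(sim$video)
  expect_equal(round(al$shifts$dy), sim$truth$shifts[, 1])
  expect_equal(round(al$shifts$dx), sim$truth$shifts[, 2])
})

test_that("local median distance matches closed forms and a brute-force oracle", {
  # identical frames -> all distances zero
  frames <- array(0.7, dim = c(6, 6, 8))
  expect_equal(local_median_distance(vp_video(frames), 71), rep(0, 8))
  # one black frame in a constant bright sequence
  frames[, , 4] <- 0
  ed <- local_median_distance(vp_video(frames), 71)
  expect_equal(ed[4], sqrt(36) * 0.7)
  expect_equal(ed[-4], rep(0, 7))
  # random toy sequence vs brute-force per-pixel median, window 3
  set.seed(41)
  toy <- array(runif(8 * 8 * 5), dim = c(8, 8, 5))
  expect_equal(local_median_distance(vp_video(toy), 3),
               ref_local_median_distance(toy, 3))
  # reordering frames far outside the window leaves local distances unchanged
  toy2 <- toy[, , c(5, 2, 3, 4, 1)]
  expect_equal(local_median_distance(vp_video(toy), 3)[3],
               local_median_distance(vp_video(toy2), 3)[3])
})

test_that("VP extraction is the masked frame mean and is linear", {
  frames <- array(0, dim = c(4, 4, 3))
  for (i in 1:3) frames[, , i] <- i / 10
  roi <- matrix(FALSE, 4, 4); roi[2:3, 2:3] <- TRUE
  v <- vp_video(frames)
  expect_equal(extract_vp_signal(v, roi)$i_vp, c(0.1, 0.2, 0.3))
  one <- matrix(FALSE, 4, 4); one[1, 1] <- TRUE
  expect_equal(extract_vp_signal(v, one)$i_vp, frames[1, 1, ])
  # linearity: a*video + b -> a*i_vp + b
  v2 <- vp_video(frames * 3 + 0.05)
  expect_equal(extract_vp_signal(v2, roi)$i_vp,
               extract_vp_signal(v, roi)$i_vp * 3 + 0.05)
  expect_error(extract_vp_signal(v, matrix(FALSE, 4, 4)),
               class = "veinpulse_input_error")
  expect_error(extract_vp_signal(v, matrix(TRUE, 5, 5)),
               class = "veinpulse_input_error")
})

test_that("distorted-frame detection flags injected blinks and manual extras", {
  cfg <- sim_config(duration = 8, blink_count = 3, noise_sd = 0.01,
                    drift_amplitude = 0, seed = 14)
  sim <- simulate_subject(cfg)
  dd <- detect_distorted_frames(sim$video, alpha = 0.05)
  expect_identical(which(dd$report$flagged), sim$truth$distorted_frame_indices)
  expect_identical(which(!dd$video$valid), sim$truth$distorted_frame_indices)
  # manual refinement list is unioned in
  dd2 <- detect_distorted_frames(sim$video, alpha = 0.05, manual_bad = 7L)
  expect_true(7L %in% which(dd2$report$flagged))
})

test_that("clean video yields no (or alpha-consistent) spurious flags", {
  cfg <- sim_config(duration = 8, noise_sd = 0.01, drift_amplitude = 0, seed = 15)
  sim <- simulate_subject(cfg)
  dd <- detect_distorted_frames(sim$video, alpha = 0.05)
  expect_lte(sum(dd$report$flagged), ceiling(0.05 * sim$video$n_frames))
})
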