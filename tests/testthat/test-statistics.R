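test_that("SDRR closed forms and generator consistency", {
  expect_equal(compute_sdrr(rep(0.9, 6)), 0)
  expect_equal(compute_sdrr(c(0.8, 1.0)), sqrt(0.02), tolerance = 1e-12)
  expect_error(compute_sdrr(0.9), class = "veinpulse_input_error")
  # implied RR dispersion: sd_RR ~ hr_sd * 60 / hr_mean^2
  sdrr <- sapply(1:20, function(s) {
    tr <- generate_ecg(sim_config(duration = 12, hr_mean = 64, hr_sd = 3,
                                  seed = 300 + s))$truth
    compute_sdrr(diff(tr$r_wave_times))
  })
  implied <- 3 * 60 / 64^2
  se <- sd(sdrr) / sqrt(length(sdrr))
  expect_lt(abs(mean(sdrr) - implied), 3 * se + 0.002)
})

test_that("Spearman correlation: exact cases and agreement with stats::cor.test", {
  expect_equal(spearman_cor(1:5, c(2, 4, 9, 16, 25))$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  set.seed(9)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  mine <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  # invariance under strictly monotone transforms of either input
  expect_equal(spearman_cor(exp(x), y^3)$rho, mine$rho)
})

test_that("Spearman handles degenerate input", {
  expect_warning(res <- spearman_cor(rep(1, 10), rnorm(10)))
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:2, 1:2), class = "veinpulse_input_error")
})

test_that("Spearman null calibration at the cohort size", {
  set.seed(202)
  n_rep <- 1000
  res <- replicate(n_rep, {
    r <- spearman_cor(rnorm(13), rnorm(13))
    c(r$rho, r$p_value)
  })
  expect_lt(abs(mean(res[1, ])), 0.03)
  rate <- mean(res[2, ] < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se + 0.005)
})

test_that("subject summary uses Tukey quartiles and ignores cycle order", {
  cyc <- tibble::tibble(subject_id = "A", tvc_ms = c(100, 120, 140),
                        tvc_rel_pct = c(10, 12, 14))
  s <- subject_summary(cyc)
  a <- s[s$subject_id == "A", ]
  expect_equal(a$tvc_ms_median, 120)
  expect_equal(c(a$tvc_ms_q1, a$tvc_ms_q3), c(110, 130))
  perm <- cyc[c(3, 1, 2), ]
  expect_equal(subject_summary(perm), s)
  # subject with no valid cycles is dropped with a warning
  cyc2 <- dplyr::bind_rows(
    dplyr::mutate(cyc, valid = TRUE),
    tibble::tibble(subject_id = "B", tvc_ms = 1, tvc_rel_pct = 1, valid = FALSE))
  expect_warning(s2 <- subject_summary(cyc2), "B")
  expect_false("B" %in% s2$subject_id)
})

test_that("cycle scatter flattens cohorts and reports the pooled correlation", {
  one <- tibble::tibble(subject_id = "A", rr_s = 0.9, tvc_ms = 120)
  cs <- cycle_scatter(one)
  expect_equal(nrow(cs$table), 1)
  expect_true(is.na(cs$correlation$rho))
  co <- simulate_cohort(n_subjects = 6, duration = 10, seed = 5)
  cs2 <- cycle_scatter(co$cycles)
  expect_equal(nrow(cs2$table), nrow(co$cycles))
  expect_true(abs(cs2$correlation$rho) <= 1)
})

test_that("delays tied to cycle length give a strong positive correlation", {
  co <- simulate_cohort(n_subjects = 13, seed = 7,
                        delay_fraction_of_rr = 0.2, noise_sd = 0)
  expect_gt(cycle_scatter(co$cycles)$correlation$rho, 0.9)
})

test_that("covariate screen returns one row per covariate", {
  set.seed(33)
  subj <- tibble::tibble(subject_id = sprintf("S%02d", 1:13),
                         tvc_ms = runif(13, 60, 220),
                         systolic_bp = rnorm(13, 125, 10),
                         age = runif(13, 25, 60))
  cc <- covariate_correlations(subj)
  expect_equal(cc$covariate, c("systolic_bp", "age"))
  expect_true(all(abs(cc$rho) <= 1))
  cc_h <- covariate_correlations(subj, adjust = "holm")
  expect_true(all(cc_h$p_value >= cc$p_value))
})
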