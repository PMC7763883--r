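test_that("morphology invariants are enforced", {
  m <- fixed_morphology()
  expect_s3_class(m, "subject_morphology")
  bad <- m
  expect_error(subject_morphology(replace(m$amp, "R", 0.1), m$width, m$center,
                                  0.75, 0.5), "exceed")
  expect_error(subject_morphology(m$amp, m$width, m$center, 0.5, 0.75),
               "tachycardia")
  expect_error(synth_cycle(m, "sideways", 500))
})

test_that("one cycle has the forced length and a zero signal stays zero", {
  m <- fixed_morphology()
  cyc <- synth_cycle(m, "pre", 2000)
  expect_length(cyc, 1500)  # round(0.75 * 2000)
  # zero-amplitude morphology (built raw: the constructor demands R > 0)
  m0 <- structure(list(amp = c(P = 0, Q = 0, R = 0, S = 0, T = 0),
                       width = m$width, center = m$center,
                       rr_rest = 0.75, rr_post = 0.5),
                  class = "subject_morphology")
  expect_equal(as.numeric(synth_cycle(m0, "pre", 2000)), rep(0, 1500))
})

test_that("QRS samples are identical across states (tachycardia spares the QRS)", {
  m <- fixed_morphology()
  rs <- 2000
  pre <- synth_cycle(m, "pre", rs)
  post <- synth_cycle(m, "post", rs)
  w <- round(0.025 * rs)
  near_r <- function(x) {
    r <- attr(x, "r_index")
    as.numeric(x[(r - w):(r + w)])
  }
  expect_lt(max(abs(near_r(pre) - near_r(post))), 1e-9)
  # and the P/T apexes move toward R after exercise
  r_pre <- attr(pre, "r_index"); r_post <- attr(post, "r_index")
  p_pre <- which.max(pre[1:(r_pre - 100)]); p_post <- which.max(post[1:(r_post - 100)])
  expect_lt(r_post - p_post, r_pre - p_pre)
  t_pre <- which.max(pre[(r_pre + 150):length(pre)])
  t_post <- which.max(post[(r_post + 150):length(post)])
  expect_lt(t_post, t_pre)
})

test_that("records carry exact ground truth and are seeded-reproducible", {
  m <- fixed_morphology()
  cfg <- cohort_config(n_subjects = 1, n_sessions = 1, rs = 500,
                       noise_sd = 0, wander_amp = 0, seed = 7)
  rec <- synth_record(m, "pre", 7.5, cfg, seed = 7)
  expect_length(rec$r_peaks, 10)  # floor(7.5 / 0.75)
  expect_length(rec$samples, 7.5 * 500)
  # rate contract across a few durations
  for (dur in c(3, 5.2, 9.9)) {
    r2 <- synth_record(m, "post", dur, cfg, seed = 1)
    expect_length(r2$r_peaks, floor(dur / m$rr_post))
  }
  cfg_noisy <- cohort_config(n_subjects = 1, n_sessions = 1, rs = 500,
                             snr_db = 20, seed = 3)
  a <- synth_record(m, "pre", 10, cfg_noisy, seed = 11)
  b <- synth_record(m, "pre", 10, cfg_noisy, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_error(synth_record(m, "pre", 0.2, cfg), "RR")
})

test_that("baseline wander is the configured sinusoid", {
  m <- fixed_morphology()
  cfg <- cohort_config(n_subjects = 1, n_sessions = 1, rs = 500,
                       noise_sd = 0, wander_amp = 0.2, wander_freq = 0.3,
                       seed = 5)
  rec <- synth_record(m, "pre", 20, cfg, seed = 5)
  resid <- rec$samples - rec$clean
  tt <- (seq_along(resid) - 1) / 500
  fit <- lm(resid ~ sin(2 * pi * 0.3 * tt) + cos(2 * pi * 0.3 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 0.2, tolerance = 1e-6)
  expect_lt(sd(resid(fit)), 1e-9)
})

test_that("cohorts reuse subject morphology and differ between subjects", {
  cfg <- cohort_config(n_subjects = 4, n_sessions = 2, duration_pre = 3,
                       duration_post = 2, rs = 500, seed = 21)
  coh <- synth_cohort(cfg)
  expect_length(coh$records, 16)  # subjects x sessions x 2 states
  expect_false(identical(coh$morphologies[[1]]$amp, coh$morphologies[[2]]$amp))
  # same subject, both sessions and states, share one morphology object
  s1 <- Filter(function(r) r$subject == "s01", coh$records)
  expect_length(s1, 4)
  # identical config (including seed) regenerates the identical cohort
  coh2 <- synth_cohort(cfg)
  expect_identical(coh$records[[1]]$samples, coh2$records[[1]]$samples)
  expect_identical(coh$morphologies, coh2$morphologies)
})
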