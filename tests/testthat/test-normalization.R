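test_that("interpolation counts follow the duration arithmetic", {
  expect_equal(interpolation_count(2000, 0.12, 0.08), list(dn = 240L, dr = 160L, ni = 80L))
  expect_equal(interpolation_count(500, 0.2, 0.2)$ni, 0L)
  expect_equal(interpolation_count(100, 0.10, 0.06)$ni, 4L)
  expect_error(interpolation_count(500, -0.1, 0.2), "positive")
})

test_that("insertion positions follow the truncated uniform-step formula", {
  expect_equal(interpolation_positions(8, 2), c(3L, 5L))
  expect_equal(interpolation_positions(11, 0), integer(0))
  expect_equal(interpolation_positions(6, 1), 4L)
  expect_error(interpolation_positions(4, 8), class = "ecgfuse_step_underflow")
  # positions match the oracle and stay within [2, dr] wherever one pass works
  for (dr in c(5, 9, 17, 30)) for (ni in 0:(dr - 1)) {
    pos <- interpolation_positions(dr, ni)
    expect_identical(pos, as.integer(oracle_positions(dr, ni)))
    if (ni > 0) expect_true(min(pos) >= 2 && max(pos) <= dr)
  }
})

test_that("inserted amplitudes are neighbor averages", {
  expect_equal(interpolate_wave(c(1, 3), 2L), c(1, 2, 3))
  w <- rep(4.2, 9)
  expect_equal(interpolate_wave(w, interpolation_positions(9, 4)), rep(4.2, 13))
  set.seed(11)
  w2 <- rnorm(8)
  out <- interpolate_wave(w2, interpolation_positions(8, 2))
  expect_length(out, 10)
  expect_identical(out, oracle_insert_pass(w2, oracle_positions(8, 2)))
})

test_that("expansion matches the brute-force oracle and keeps its invariants", {
  set.seed(23)
  for (rep_i in 1:40) {
    dr <- sample(3:30, 1)
    ni <- sample(0:(dr - 1), 1)
    w <- rnorm(dr)
    out <- interpolate_wave(w, interpolation_positions(dr, ni))
    expect_identical(out, oracle_insert_pass(w, oracle_positions(dr, ni)))
    # subsequence property: the original samples survive in order
    idx <- match(w, out)
    expect_true(!anyNA(idx) && !is.unsorted(idx, strictly = TRUE))
    # boundedness: inserted values lie within the enclosing original interval
    ins <- setdiff(seq_along(out), idx)
    for (j in ins) {
      expect_gte(out[j], min(out[j - 1], out[j + 1]) - 1e-12)
      expect_lte(out[j], max(out[j - 1], out[j + 1]) + 1e-12)
    }
  }
})

test_that("resizing reaches any target through repeated passes", {
  set.seed(31)
  w <- rnorm(6)
  big <- resize_wave(w, 40)             # ni >= dr: multiple passes
  expect_length(as.numeric(big), 40)
  expect_gt(attr(big, "passes"), 1)
  idx <- match(w, big)
  expect_true(!anyNA(idx) && !is.unsorted(idx))
  small <- resize_wave(rnorm(30), 11)   # contraction via uniform deletion
  expect_length(as.numeric(small), 11)
  expect_error(resize_wave(rnorm(5), 1), "at least 2")
})

test_that("time normalization hits the target lengths and copies the QRS bit-exactly", {
  set.seed(41)
  split <- structure(list(p = rnorm(40), qrs = rnorm(55), t = rnorm(80),
                          tr_p = 40 / 500, tr_t = 80 / 500, rs = 500),
                     class = "wave_split")
  # targets equal to the actual durations: identity
  spec0 <- normalization_spec(tn_p = 40 / 500, tn_t = 80 / 500, rs = 500,
                              mode = "time")
  expect_identical(time_normalize_cycle(split, spec0),
                   structure(c(split$p, split$qrs, split$t), ni_p = 0L, ni_t = 0L))
  # expansion to a pre-exercise-like target
  spec1 <- normalization_spec(tn_p = 75 / 500, tn_t = 150 / 500, rs = 500,
                              mode = "time")
  y <- time_normalize_cycle(split, spec1)
  expect_length(as.numeric(y), 75 + 55 + 150)
  expect_identical(as.numeric(y)[76:130], split$qrs)
  expect_error(time_normalize_cycle(split,
                                    normalization_spec(rs = 500, mode = "frequency")),
               "mode")
})

test_that("frequency normalization keeps the band and rejects invalid bands", {
  rs <- 500
  tt <- (0:(6 * rs - 1)) / rs
  core <- (rs):(5 * rs)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(frequency_normalize(rep(0, 1000), rs), rep(0, 1000))
  slow <- sin(2 * pi * 2 * tt)
  expect_lt(rms(frequency_normalize(slow, rs)[core]), 0.1 * rms(slow[core]))
  mid <- sin(2 * pi * 40 * tt)
  expect_equal(rms(frequency_normalize(mid, rs)[core]), rms(mid[core]),
               tolerance = 0.1)
  expect_error(normalization_spec(rs = 500, band = c(10, 400)), "rs/2")
})

test_that("band search minimizes pre/post distance with widest-band tie-break", {
  set.seed(51)
  rs <- 500
  n <- 300
  base <- matrix(rnorm(5 * n), 5)
  # singleton grid returns the single candidate
  b1 <- select_optimal_band(base, base, rs, lows = 10, highs = 80)
  expect_equal(as.numeric(b1), c(10, 80))
  # identical cycles: every band gives 0, the widest candidate wins
  b2 <- select_optimal_band(base, base, rs, lows = c(5, 10), highs = c(60, 80))
  expect_equal(as.numeric(b2), c(5, 80))
  # pre/post differing only by a slow 5 Hz component: chosen low cutoff > 5
  tt <- (0:(n - 1)) / rs
  drift <- matrix(rep(0.8 * sin(2 * pi * 5 * tt), 5), 5, byrow = TRUE)
  b3 <- select_optimal_band(base, base + drift, rs,
                            lows = c(2, 8, 12), highs = c(60, 80))
  expect_gt(b3[["low"]], 5)
  expect_error(select_optimal_band(base, base, rs, lows = 90, highs = 80),
               "empty")
})

test_that("fusion brings post-exercise cycles toward the pre-exercise template", {
  prep <- study_prep(1, n_subjects = 5)
  raw <- study_set(1, "none", 5)
  fus <- study_set(1, "fusion", 5)
  d_raw <- as.numeric(average_similarity(pre_of(raw), post_of(raw), 20))
  d_fus <- as.numeric(average_similarity(pre_of(fus), post_of(fus), 20))
  expect_lt(d_fus, d_raw)
  # mode switches: time skips the bandpass, frequency skips the interpolation
  tim <- study_set(1, "time", 5)
  fre <- study_set(1, "frequency", 5)
  expect_equal(ncol(tim$cycles), ncol(fus$cycles))
  expect_equal(ncol(fre$cycles), ncol(raw$cycles))
  expect_false(identical(tim$cycles, fus$cycles))
})
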