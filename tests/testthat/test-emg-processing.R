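test_that("rectify_and_smooth obeys RMS identities and matches direct summation", {
  # all-zero input stays zero
  expect_equal(rectify_and_smooth(numeric(100), 1000)$values, numeric(100))
  # constant input: RMS of a constant is its absolute value
  expect_equal(rectify_and_smooth(rep(-7, 200), 1926)$values, rep(7, 200))
  # 200-ms square pulse at amplitude A in zero background: interior A,
  # half-covered window A/sqrt(2); verified against a per-sample oracle
  rate <- 1000
  raw <- c(rep(0, 300), rep(4, 200), rep(0, 300))
  env <- rectify_and_smooth(raw, rate, rms_window_s = 0.020)
  expect_equal(env$values, oracle_rms(raw, rate, 0.020))
  expect_equal(env$values[350], 4)              # pulse interior
  expect_equal(env$values[301], 4 / sqrt(2), tolerance = 0.03)  # half-covered
  # random signal agrees with the oracle everywhere, edges included
  set.seed(1)
  raw2 <- rnorm(500, sd = 5)
  expect_equal(rectify_and_smooth(raw2, rate)$values,
               oracle_rms(raw2, rate, 0.020))
  expect_error(rectify_and_smooth(numeric(0), 1000), "empty")
})

test_that("baseline estimation finds quiet fragments and the windowed minimum", {
  rate <- 200
  # constant envelope: floor = level = value, one segment spanning the trial
  b <- estimate_baseline(make_env(rep(5, 2 * rate), rate))
  expect_equal(b$floor_uv, 5)
  expect_equal(b$level_uv, 5)
  expect_equal(nrow(b$segments), 1L)
  expect_equal(b$segments$t_start, 0)
  expect_equal(b$segments$t_end, 2)
  # piecewise: 2 s at 4, 0.3 s burst at 40, 2 s at 4 -> oracle agreement,
  # level near 4, burst bulk excluded from the quiet coverage
  vals <- piecewise(c(4, 2 * rate), c(40, 0.3 * rate), c(4, 2 * rate))
  b2 <- estimate_baseline(make_env(vals, rate))
  o <- oracle_baseline(vals, rate)
  expect_equal(b2$floor_uv, o$floor_uv)
  expect_equal(b2$level_uv, o$level_uv)
  expect_equal(b2$floor_uv, 4)
  expect_lt(b2$level_uv, 1.2 * 4)
  burst_idx <- 2 * rate + seq_len(0.3 * rate)
  expect_lt(mean(o$covered[burst_idx]), 0.1)
  # strictly increasing ramp: single starting segment, oracle agreement
  ramp <- seq(1, 30, length.out = 3 * rate)
  b3 <- estimate_baseline(make_env(ramp, rate))
  o3 <- oracle_baseline(ramp, rate)
  expect_equal(nrow(b3$segments), 1L)
  expect_equal(b3$segments$t_start, 0)
  expect_equal(b3$level_uv, o3$level_uv)
  expect_error(estimate_baseline(make_env(rep(1, 50), rate)), "shorter")
})

test_that("burst detection applies threshold, duration and merge rules", {
  rate <- 1000
  # envelope never above twice baseline -> nothing
  env <- make_env(rep(9.9, 2000), rate)  # baseline 5 -> threshold 10
  expect_equal(nrow(detect_bursts(env, 5)), 0L)
  # ties fall below threshold (strict inequality)
  expect_equal(nrow(detect_bursts(make_env(rep(10, 2000), rate), 5)), 0L)
  # one 100-ms run at 12 uV over baseline 5 -> one burst of 100 ms
  vals <- piecewise(c(5, 1000), c(12, 100), c(5, 1000))
  b <- detect_bursts(make_env(vals, rate), 5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_s, 0.1)
  expect_equal(b$t_onset, 1.0)
  expect_equal(b$mean_amp_uv, 12)
  # two 40-ms runs at 15 uV with a 40-ms gap merge into one 120-ms response
  v2 <- piecewise(c(5, 1000), c(15, 40), c(5, 40), c(15, 40), c(5, 1000))
  b2 <- detect_bursts(make_env(v2, rate), 5)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$duration_s, 0.12)
  # with a 60-ms gap they stay separate
  v3 <- piecewise(c(5, 1000), c(15, 40), c(5, 60), c(15, 40), c(5, 1000))
  expect_equal(nrow(detect_bursts(make_env(v3, rate), 5)), 2L)
})

test_that("burst detection equals the brute-force oracle on exhaustive small patterns", {
  # all boolean patterns of up to 10 samples at a 100 Hz coarse rate
  # (30 ms = 3 samples to keep, gaps of up to 4 samples merge)
  for (nbits in c(5L, 10L)) {
    for (int in 0:(2^nbits - 1)) {
      pat <- ((int %/% 2^(0:(nbits - 1))) %% 2) > 0
      det <- detect_bursts(make_env(pat * 20, 100), 5)
      o <- oracle_keep_merge(pat, min_len = 3L, max_gap = 4L)
      expect_equal(nrow(det), nrow(o))
      if (nrow(o)) {
        expect_equal(round(det$t_onset * 100) + 1L, unname(o[, "start"]))
        expect_equal(round(det$t_offset * 100), unname(o[, "end"]))
      }
    }
  }
})

test_that("burst invariants hold on random envelopes and threshold is monotone", {
  set.seed(7)
  rate <- 500
  for (rep_i in 1:25) {
    vals <- abs(5 + stats::arima.sim(list(ar = 0.95), 3 * rate, sd = 3))
    env <- make_env(as.numeric(vals), rate)
    base <- estimate_baseline(env)
    prev_total <- Inf
    for (fac in c(1.5, 2, 3)) {
      b <- detect_bursts(env, base, burst_factor = fac)
      if (nrow(b) > 1) {
        expect_true(all(diff(b$t_onset) > 0))
        expect_true(all(b$t_onset[-1] - b$t_offset[-nrow(b)] >= 0.050))
      }
      if (nrow(b)) {
        expect_true(all(b$duration_s >= 0.030))
        expect_true(all(b$t_offset > b$t_onset))
      }
      tot <- sum(b$duration_s)
      expect_lte(tot, prev_total)  # raising the factor never adds burst time
      prev_total <- tot
    }
  }
})

test_that("bursts are recovered exactly from well-separated synthetic envelopes", {
  # spot check of the full recovery experiment (acceptance runs 200 seeds)
  for (seed in 1:10) {
    ge <- generate_burst_envelope(duration_s = 12, seed = seed)
    base <- estimate_baseline(ge$envelope)
    b <- detect_bursts(ge$envelope, base)
    expect_equal(nrow(b), nrow(ge$truth))
    expect_true(all(abs(b$t_onset - ge$truth$t_onset) <= 0.010))
  }
})
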