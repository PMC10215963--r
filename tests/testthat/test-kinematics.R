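straight_traj <- function(speed_cms = 30, dur_s = 1, rate = 50, pad_s = 1,
                          height = 60) {
  np <- pad_s * rate
  nm <- dur_s * rate
  x <- c(rep(0, np), cumsum(rep(speed_cms / rate, nm)),
         rep(speed_cms * dur_s, np))
  trajectory(cbind(x, 0 * x), rate_hz = rate, limb = "left_leg",
             body_height_cm = height)
}

test_that("speed computation matches kinematic identities", {
  rate <- 50
  # stationary trajectory -> all-zero speed
  tr0 <- trajectory(matrix(3, 100, 2), rate, "left_leg", 60)
  expect_equal(compute_speed(tr0), numeric(100))
  # uniform straight motion at 30 cm/s -> 0.3 m/s in the interior
  tr <- straight_traj()
  v <- compute_speed(tr)
  interior <- 60:90  # inside the moving segment, away from smoothing edges
  expect_equal(v[interior], rep(0.3, length(interior)), tolerance = 1e-9)
  # circular motion of radius r at angular rate w -> speed ~ r*w
  r_cm <- 10; w <- 2 * pi / 2  # one revolution per 2 s
  tt <- (0:400) / 100
  trc <- trajectory(cbind(r_cm * cos(w * tt), r_cm * sin(w * tt)),
                    rate_hz = 100, limb = "right_arm", body_height_cm = 60)
  vc <- compute_speed(trc, smooth_window_s = 0.05)
  expect_equal(vc[50:350], rep(r_cm * w / 100, 301), tolerance = 1e-3)
  expect_error(compute_speed(trajectory(matrix(0, 1, 2), 50, "left_leg", 60)),
               "too short")
})

test_that("movement-unit rules: threshold, duration, merge, excursion", {
  cfg <- pipeline_config()
  # stationary -> no MUs
  expect_equal(nrow(detect_mus(straight_traj(0))), 0L)
  # 1.0-s straight movement at 0.3 m/s covers 30 cm >= 15% of 60 cm -> one MU
  mus <- detect_mus(straight_traj())
  expect_equal(nrow(mus), 1L)
  expect_equal(mus$duration_s, 1.0, tolerance = 0.35)
  expect_gt(mus$excursion_x_cm, 0.15 * 60)
  expect_gt(mus$peak_speed_mps, 0.2)
  # rapid small oscillation: fast but only 2 cm of excursion -> rejected
  rate <- 50
  osc <- 1 * sin(2 * pi * 8 * (0:200) / rate)  # 2-cm peak-to-peak, fast
  tro <- trajectory(cbind(c(rep(0, 50), osc, rep(0, 50)), numeric(301)),
                    rate, "left_leg", 60)
  expect_gt(max(compute_speed(tro)), 0.2)
  expect_equal(nrow(detect_mus(tro)), 0L)
  # two 0.4-s movements with a 0.3-s pause merge (gap < 0.5 s)
  seg <- function(v, n) rep(v / rate, n)
  x2 <- cumsum(c(rep(0, 50), seg(40, 20), rep(0, 15), seg(40, 20), rep(0, 50)))
  tr2 <- trajectory(cbind(x2, 0 * x2), rate, "left_leg", 60)
  m2 <- detect_mus(tr2)
  expect_equal(nrow(m2), 1L)
  # a 0.8-s pause keeps them separate (each covers 16 cm >= 9 cm)
  x3 <- cumsum(c(rep(0, 50), seg(40, 20), rep(0, 40), seg(40, 20), rep(0, 50)))
  tr3 <- trajectory(cbind(x3, 0 * x3), rate, "left_leg", 60)
  m3 <- detect_mus(tr3)
  expect_equal(nrow(m3), 2L)
})

test_that("invalid spans are barriers for runs and merging", {
  rate <- 50
  seg <- function(v, n) rep(v / rate, n)
  x <- cumsum(c(rep(0, 50), seg(40, 20), rep(0, 10), seg(40, 20), rep(0, 50)))
  valid <- rep(TRUE, length(x))
  valid[75] <- FALSE  # inside the 0.2-s gap between the two pulses
  tr <- trajectory(cbind(x, 0 * x), rate, "left_leg", 60, valid = valid)
  m <- detect_mus(tr)
  trv <- trajectory(cbind(x, 0 * x), rate, "left_leg", 60)
  mv <- detect_mus(trv)
  expect_equal(nrow(mv), 1L)   # without the barrier the pulses merge
  expect_equal(nrow(m), 2L)    # the barrier keeps them apart
})

test_that("detect_mus equals the brute-force interval oracle on short trajectories", {
  set.seed(21)
  rate <- 10  # coarse rate so runs/gaps span few samples
  cfg <- pipeline_config()
  for (rep_i in 1:300) {
    n <- sample(20:100, 1)
    state <- stats::filter(rnorm(n), rep(1, 4), sides = 1)
    state[is.na(state)] <- 0
    sp <- pmax(0, 0.25 + 0.25 * as.numeric(state))
    step <- sp * 100 / rate  # cm per frame consistent with the speed scale
    ang <- cumsum(rnorm(n, 0, 0.3))
    xy <- cbind(cumsum(step * cos(ang)), cumsum(step * sin(ang)))
    valid <- runif(n) > 0.05
    height <- sample(c(20, 40, 60), 1)
    tr <- trajectory(xy, rate, "left_leg", height, valid = valid)
    mus <- detect_mus(tr, speed = sp, cfg = cfg)
    o <- oracle_mus(xy, sp, valid, rate, height)
    expect_equal(nrow(mus), nrow(o))
    if (nrow(o)) {
      expect_equal(round(mus$t_onset * rate) + 1, unname(o[, "start"]))
      expect_equal(round(mus$t_offset * rate), unname(o[, "end"]))
    }
  }
})

test_that("MU invariants hold and the alternative criteria are not stricter", {
  set.seed(3)
  cfg_main <- pipeline_config()
  cfg_alt <- pipeline_config(mu_criteria = "alternative")
  expect_equal(cfg_alt$mu_min_dur_s, 0.1)
  expect_equal(cfg_alt$mu_merge_gap_s, 0.3)
  expect_equal(cfg_alt$mu_excursion_frac, 0.10)
  for (seed in 1:8) {
    sess <- generate_spontaneous_session(
      spontaneous_gen_params(session_dur_s = 60, limbs = "left_leg",
                             mu_rate_per_min = 8, min_gap_s = 0.6,
                             with_emg = FALSE, seed = seed))
    tr <- sess$trajectories$left_leg
    m_main <- detect_mus(tr, cfg = cfg_main)
    m_alt <- detect_mus(tr, cfg = cfg_alt)
    if (nrow(m_main) > 1) {
      expect_true(all(diff(m_main$t_onset) > 0))
      expect_true(all(m_main$t_onset[-1] >= m_main$t_offset[-nrow(m_main)]))
    }
    expect_true(all(m_main$duration_s > cfg_main$mu_min_dur_s))
    expect_true(all(m_main$peak_speed_mps > cfg_main$mu_speed_threshold_mps))
    expect_true(all(pmax(m_main$excursion_x_cm, m_main$excursion_y_cm) >=
                      cfg_main$mu_excursion_frac * tr$body_height_cm))
    # pulses are separated by > 0.5 s here, so every alternative threshold
    # is weaker and the alternative set can only find more episodes
    expect_gte(nrow(m_alt), nrow(m_main))
  }
})

test_that("merge_first ordering lets sub-duration fragments seed an episode", {
  rate <- 50
  # two 0.18-s speed pulses (below the 0.2-s duration rule) 0.2 s apart,
  # supplied directly so the ordering question is isolated from smoothing
  sp <- c(rep(0, 50), rep(0.6, 9), rep(0, 10), rep(0.6, 9), rep(0, 50))
  x <- cumsum(sp * 100 / rate)
  tr <- trajectory(cbind(x, 0 * x), rate, "left_leg", 60)
  expect_equal(nrow(detect_mus(tr, speed = sp)), 0L)  # default order drops both
  m <- detect_mus(tr, speed = sp, cfg = pipeline_config(merge_first = TRUE))
  expect_equal(nrow(m), 1L)               # merged first, they survive
})

test_that("separated flag follows the 25% overlap rule", {
  m <- data.frame(limb = c("left_leg", "right_leg"),
                  t_onset = c(0, 0.9), t_offset = c(1, 1.9),
                  duration_s = c(1, 1))
  r <- classify_separated(m)
  expect_equal(r$overlap_s, c(0.1, 0.1))
  expect_true(all(r$separated))  # 10% < 25%
  m$t_onset[2] <- 0.5; m$t_offset[2] <- 2.0
  r2 <- classify_separated(m)
  expect_false(r2$separated[1])  # 50% overlap
  # no MUs on other limbs -> separated
  r3 <- classify_separated(m[1, ])
  expect_true(r3$separated)
  # union mode accumulates overlap across several other-limb MUs
  m4 <- data.frame(limb = c("left_leg", "right_leg", "right_arm"),
                   t_onset = c(0, 0, 0.8), t_offset = c(1, 0.15, 1.0),
                   duration_s = c(1, 0.15, 0.2))
  expect_true(classify_separated(m4)$separated[1])            # max = 0.2
  expect_false(classify_separated(m4, overlap_mode = "union")$separated[1])
})

test_that("MU summaries compute frequency and side averages", {
  mus <- data.frame(limb = c(rep("left_leg", 8), rep("right_leg", 16)),
                    duration_s = rep(1.25, 24),
                    t_onset = 1:24, t_offset = 1:24 + 1.25)
  s <- summarize_mus(mus, session_duration_s = 120)
  leg <- s[s$limb_class == "leg", ]
  expect_equal(leg$freq_per_min, 6)   # (4 + 8) / 2 MU/min
  expect_equal(leg$mean_duration_s, 1.25)
  s2 <- summarize_mus(mus[1:12, ], 60)
  expect_equal(s2$n_mus, 12L)
  expect_equal(s2$freq_per_min, 6)    # 12 MUs in 120 s equivalent
  expect_error(summarize_mus(mus, 0), "positive")
})
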