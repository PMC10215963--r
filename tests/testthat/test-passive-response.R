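test_that("default stretch map encodes the biarticular thigh geometry", {
  m <- default_stretch_map()
  # RF is lengthened by knee flexion and shortened by hip flexion
  expect_equal(stretch_state(m, "knee", "flexion", "RF"), "stretching")
  expect_equal(stretch_state(m, "hip", "flexion", "RF"), "shortening")
  expect_equal(stretch_state(m, "hip", "extension", "BF"), "shortening")
  expect_equal(stretch_state(m, "knee", "flexion", "BF"), "shortening")
  # GL is biarticular: deliberately uninterpreted for knee movements
  expect_equal(stretch_state(m, "knee", "flexion", "GL"), "unaffected")
  expect_equal(stretch_state(m, "ankle", "flexion", "TA"), "shortening")
  expect_equal(stretch_state(m, "elbow", "flexion", "BB"), "shortening")
  expect_equal(stretch_state(m, "elbow", "extension", "TB"), "shortening")
  # every moved (joint, direction) names one stretched and one shortened muscle
  for (j in unique(m$joint)) {
    for (d in c("flexion", "extension")) {
      st <- m$state[m$joint == j & m$direction == d]
      expect_true("stretching" %in% st && "shortening" %in% st)
    }
  }
  expect_error(stretch_map("knee", "flexion", "RF", "stretching"),
               "shortening")
})

make_bursts <- function(muscle, side, t_onset, t_offset) {
  data.frame(muscle = muscle, side = side, t_onset = t_onset,
             t_offset = t_offset, mean_amp_uv = rep(12, length(t_onset)),
             stringsAsFactors = FALSE)
}

test_that("response classification computes kind, latency and truncated duration", {
  ph <- phase_annotation("knee", "L", c("flexion", "extension"),
                         c(0, 1.5), c(1.5, 3.0))
  # RF burst 0.3 s into a 1.5-s knee flexion, ending inside the phase
  r <- classify_responses(make_bursts("RF", "L", 0.3, 0.5), ph)
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "StR")
  expect_equal(r$latency_ms, 300)
  expect_equal(r$latency_pct, 20)
  expect_equal(r$duration_s, 0.2)
  expect_equal(r$duration_pct, 200 / 15)
  # truncated duration of 0.08 s is below the 100-ms rule -> no response
  expect_equal(nrow(classify_responses(make_bursts("RF", "L", 0.3, 0.38), ph)),
               0L)
  # exactly 100 ms is not "longer than 100 ms"
  expect_equal(nrow(classify_responses(make_bursts("RF", "L", 0.3, 0.4), ph)),
               0L)
  # BF is shortened during knee flexion: 150 ms -> ShR
  r2 <- classify_responses(make_bursts("BF", "L", 0.3, 0.45), ph)
  expect_equal(r2$kind, "ShR")
  # activity persisting past the direction change: duration truncated at the
  # phase end and the burst assigned only to the phase containing its onset
  r3 <- classify_responses(make_bursts("RF", "L", 1.0, 2.2), ph)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$direction, "flexion")
  expect_equal(r3$duration_s, 0.5)
  expect_equal(r3$duration_pct, 100 * 0.5 / 1.5)
  # a long burst straddling a boundary but with <=100 ms left in its own
  # phase is not re-assigned to the next phase
  r4 <- classify_responses(make_bursts("RF", "L", 1.45, 2.2), ph)
  expect_equal(nrow(r4), 0L)
})

test_that("bursts outside phases are ignored with a message", {
  ph <- phase_annotation("knee", "L", c("flexion", "extension"),
                         c(1, 2.5), c(2.5, 4))
  expect_message(r <- classify_responses(make_bursts("RF", "L", 0.2, 0.5), ph),
                 "outside")
  expect_equal(nrow(r), 0L)
  # wrong side likewise never matches
  expect_message(
    r2 <- classify_responses(make_bursts("RF", "R", 1.2, 1.5), ph),
    "outside")
  expect_equal(nrow(r2), 0L)
})

test_that("every response lies in its phase and no burst yields two responses", {
  set.seed(11)
  ph <- phase_annotation("knee", "L", rep(c("flexion", "extension"), 10),
                         seq(0, by = 1.5, length.out = 20),
                         seq(1.5, by = 1.5, length.out = 20))
  on <- sort(runif(60, 0, 31))
  b <- make_bursts(sample(c("RF", "BF"), 60, TRUE), "L", on, on + runif(60, 0.05, 2))
  suppressMessages(r <- classify_responses(b, ph))
  expect_lte(nrow(r), nrow(b))
  pd <- as.data.frame(ph)
  for (i in seq_len(nrow(r))) {
    p <- pd[pd$phase_index == r$phase_index[i], ]
    expect_true(p$t_start <= r$t_onset[i] && r$t_onset[i] < p$t_end)
    expect_equal(p$direction, r$direction[i])
  }
  # each (onset, muscle) appears at most once
  expect_false(anyDuplicated(r[c("muscle", "t_onset")]) > 0)
})

test_that("occurrence counts movements with a response, once per phase", {
  ph <- phase_annotation("knee", "L", rep(c("flexion", "extension"), 5),
                         seq(0, by = 1.5, length.out = 10),
                         seq(1.5, by = 1.5, length.out = 10))
  # no responses -> 0%
  none <- classify_responses(make_bursts(character(0), character(0),
                                         numeric(0), numeric(0)), ph)
  occ0 <- occurrence(none, ph)
  expect_true(all(occ0$occurrence_pct == 0))
  expect_true(all(occ0$n_movements == 5))
  # responses in 3 of 5 extensions -> 60%; two bursts in one flexion count once
  b <- make_bursts("RF", "L",
                   c(1.6, 4.6, 7.6, 0.2, 0.5),
                   c(1.6, 4.6, 7.6, 0.2, 0.5) + 0.3)
  r <- classify_responses(b, ph)
  occ <- occurrence(r, ph)
  shr_ext <- occ[occ$muscle == "RF" & occ$direction == "extension", ]
  expect_equal(shr_ext$n_with_response, 3L)
  expect_equal(shr_ext$occurrence_pct, 60)
  str_flex <- occ[occ$muscle == "RF" & occ$direction == "flexion", ]
  expect_equal(str_flex$n_with_response, 1L)  # two bursts, one phase
  expect_equal(str_flex$occurrence_pct, 20)
})

test_that("occurrence pools sides symmetrically", {
  ph <- phase_annotation(rep("knee", 8), rep(c("L", "R"), each = 4),
                         rep(c("flexion", "extension"), 4),
                         rep(seq(0, by = 1.5, length.out = 4), 2),
                         rep(seq(1.5, by = 1.5, length.out = 4), 2))
  b <- rbind(make_bursts("RF", "L", 0.2, 0.5),
             make_bursts("RF", "R", c(0.2, 3.2), c(0.5, 3.5)))
  r <- classify_responses(b, ph)
  occ <- occurrence(r, ph)
  # relabel L<->R: pooled occurrence unchanged
  b2 <- b
  b2$side <- ifelse(b$side == "L", "R", "L")
  r2 <- classify_responses(b2, ph)
  occ2 <- occurrence(r2, ph)
  expect_equal(occ, occ2)
  expect_equal(occ$n_movements[1], 4L)  # 2 flexions per side, pooled
  # per-side table distinguishes them
  occ_side <- occurrence(r, ph, pool_sides = FALSE)
  expect_true("side" %in% names(occ_side))
})

test_that("latency histogram uses half-open bins and preserves mass", {
  r <- data.frame(latency_pct = rep(20, 7))
  h <- latency_histogram(r)
  expect_equal(sum(h$count), 7)
  expect_equal(h$count[h$bin_lo == 20], 7)
  expect_true(all(h$count[h$bin_lo != 20] == 0))
  # latency exactly at a break falls in the upper bin
  h2 <- latency_histogram(data.frame(latency_pct = c(10, 19.999)))
  expect_equal(h2$count[h2$bin_lo == 10], 2)
  expect_error(latency_histogram(r[0, , drop = FALSE]), "no responses")
})

test_that("rhythmic distant activity screen counts phase-locked cycles", {
  ph <- phase_annotation("hip", "L", rep(c("flexion", "extension"), 5),
                         seq(0, by = 1.5, length.out = 10),
                         seq(1.5, by = 1.5, length.out = 10))
  # a TA burst in every flexion phase -> rhythmic
  flex_on <- seq(0, by = 3, length.out = 5) + 0.4
  b <- make_bursts("TA", "L", flex_on, flex_on + 0.2)
  res <- detect_rhythmic_distant(b, ph)
  expect_true(res$rhythmic)
  expect_equal(res$n_locked, 5L)
  expect_equal(res$direction, "flexion")
  # no bursts at all -> not rhythmic
  res0 <- detect_rhythmic_distant(b[0, ], ph)
  expect_false(res0$rhythmic)
  # bursts in 2 of 6 cycles -> below the 0.5 lock fraction
  ph6 <- phase_annotation("hip", "L", rep(c("flexion", "extension"), 6),
                          seq(0, by = 1.5, length.out = 12),
                          seq(1.5, by = 1.5, length.out = 12))
  b2 <- make_bursts("TA", "L", c(0.4, 3.4), c(0.6, 3.6))
  expect_false(detect_rhythmic_distant(b2, ph6)$rhythmic)
  # fewer than min_cycles cycles: not evaluable, distinct from FALSE
  ph2 <- phase_annotation("hip", "L", c("flexion", "extension"),
                          c(0, 1.5), c(1.5, 3))
  expect_true(is.na(detect_rhythmic_distant(b, ph2)$rhythmic))
})
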