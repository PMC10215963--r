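## Synthetic sessions with complete ground truth. Raw EMG is synthesized as
## zero-mean Gaussian noise amplitude-modulated by a target envelope profile,
## so the real rectify-and-smooth path recovers the profile in expectation
## and every downstream stage can be validated by recovery experiments.
## Each output stream (phase timing, per-channel schedule and carrier noise,
## per-limb kinematics) draws from its own seeded substream derived from the
## master seed, so adding channels or limbs never perturbs existing ones.

## clamp-truncated normal draw (simple and deterministic)
.rnorm_clamped <- function(n, mean, sd, lo, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

## exact boxcar smoothing: input of length n + k - 1 -> n full-window means
.smooth_exact <- function(x, k, n) {
  cs <- cumsum(c(0, x))
  (cs[seq_len(n) + k] - cs[seq_len(n)]) / k
}

#' Parameters for synthetic passive-movement sessions
#'
#' Defaults emulate the recorded protocol: alternating flexion/extension
#' phases of about 1.5 s (SD 0.2 s) — a 3–4 s movement cycle — sampled at
#' 1926 Hz, a ~5 uV baseline envelope, and step bursts of 20 uV (4x baseline)
#' whose onsets fall uniformly between 10% and 50% of the phase duration.
#' Per phase, the lengthened muscle bursts with probability
#' `response_prob_str` and the shortened one with `response_prob_shr`.
#'
#' @param n_cycles number of flexion/extension cycles.
#' @param phase_dur_mean_s,phase_dur_sd_s phase duration distribution (s);
#'   draws are clamped to at least 0.8 s.
#' @param baseline_uv baseline envelope level (uV).
#' @param burst_amp_uv burst envelope amplitude (uV).
#' @param response_prob_str,response_prob_shr per-phase probabilities of a
#'   stretch / shortening response.
#' @param latency_pct_range onset latency range, percent of phase duration.
#' @param burst_dur_mean_s,burst_dur_sd_s burst duration distribution (s);
#'   clamped to at least 0.15 s.
#' @param noise_sd_uv rectified-Gaussian envelope noise scale (uV); 0.8
#'   matches the dispersion a 20-ms RMS window leaves on white noise.
#' @param rate_hz EMG sampling rate.
#' @param joint,side the passively moved joint and side; channels are the
#'   stretch-mapped antagonist pair of that joint.
#' @param margin_s quiet lead-in/lead-out around the movement block (s).
#' @param seed master RNG seed.
#' @return validated parameter list of class `passive_gen_params`.
#' @export
passive_gen_params <- function(n_cycles = 5L,
                               phase_dur_mean_s = 1.5, phase_dur_sd_s = 0.2,
                               baseline_uv = 5, burst_amp_uv = 20,
                               response_prob_str = 0.7,
                               response_prob_shr = 0.7,
                               latency_pct_range = c(10, 50),
                               burst_dur_mean_s = 0.4, burst_dur_sd_s = 0.1,
                               noise_sd_uv = 0.8, rate_hz = 1926,
                               joint = "knee", side = "L",
                               margin_s = 1.0, seed = 1L) {
  p <- as.list(environment())
  if (p$n_cycles < 1L) .stop_input("n_cycles must be >= 1")
  for (f in c("phase_dur_mean_s", "baseline_uv", "burst_amp_uv",
              "burst_dur_mean_s", "rate_hz", "margin_s")) {
    if (p[[f]] <= 0) .stop_input(f, " must be positive")
  }
  for (f in c("response_prob_str", "response_prob_shr")) {
    if (p[[f]] < 0 || p[[f]] > 1) .stop_input(f, " must be in [0, 1]")
  }
  if (length(p$latency_pct_range) != 2L || p$latency_pct_range[1L] < 0 ||
      p$latency_pct_range[2L] > 100 ||
      p$latency_pct_range[1L] >= p$latency_pct_range[2L]) {
    .stop_input("latency_pct_range must be an increasing pair within [0, 100]")
  }
  if (!p$joint %in% .JOINTS || !p$side %in% .SIDES) {
    .stop_input("unknown joint or side")
  }
  class(p) <- c("passive_gen_params", "list")
  p
}

#' Generate a synthetic passive-movement session
#'
#' Builds alternating flexion/extension phases, injects StR/ShR bursts into
#' the stretch-mapped antagonist pair of the moved joint, constructs the
#' envelope profile (baseline floor plus step bursts, truncated at phase
#' ends) and synthesizes raw EMG as profile-modulated Gaussian noise. The
#' ground truth records every injected burst with its kind, latency and
#' truncation state.
#'
#' @param params [passive_gen_params()].
#' @return list with `emg` ([emg_recording()]), `phases`
#'   ([phase_annotation()]), `map` (the stretch map used), and `truth`: a
#'   list with `bursts` (data.frame `channel`, `muscle`, `side`, `kind`,
#'   `phase_index`, `t_onset`, `t_offset`, `latency_pct`, `truncated`),
#'   `params` and `seed`.
#' @export
generate_passive_session <- function(params = passive_gen_params()) {
  stopifnot(inherits(params, "passive_gen_params"))
  map <- default_stretch_map()
  rate <- params$rate_hz
  ## phase timeline (stream 0)
  set.seed(.derive_seed(params$seed, 0L))
  n_phases <- 2L * params$n_cycles
  dur <- .rnorm_clamped(n_phases, params$phase_dur_mean_s,
                        params$phase_dur_sd_s, lo = 0.8)
  t_end <- params$margin_s + cumsum(dur)
  t_start <- c(params$margin_s, t_end[-n_phases])
  direction <- rep(c("flexion", "extension"), params$n_cycles)
  phases <- phase_annotation(params$joint, params$side, direction,
                             t_start, t_end)
  total_s <- t_end[n_phases] + params$margin_s
  n <- as.integer(ceiling(total_s * rate))
  ## channels: the mapped antagonist pair of the moved joint
  muscles <- sort(unique(map$muscle[map$joint == params$joint &
                                      map$state != "unaffected"]))
  channels <- paste(muscles, params$side, sep = "_")
  samples <- matrix(0, nrow = n, ncol = length(channels),
                    dimnames = list(NULL, channels))
  truth_rows <- list()
  for (ci in seq_along(channels)) {
    set.seed(.derive_seed(params$seed, ci))
    m <- muscles[ci]
    profile <- rep(params$baseline_uv, n)
    for (pi in seq_len(n_phases)) {
      st <- stretch_state(map, params$joint, direction[pi], m)
      if (st == "unaffected") next
      prob <- if (st == "stretching") params$response_prob_str else
        params$response_prob_shr
      if (stats::runif(1) >= prob) next
      lat_pct <- stats::runif(1, params$latency_pct_range[1L],
                              params$latency_pct_range[2L])
      on <- t_start[pi] + lat_pct / 100 * dur[pi]
      bdur <- .rnorm_clamped(1, params$burst_dur_mean_s,
                             params$burst_dur_sd_s, lo = 0.15)
      off <- on + bdur
      truncated <- off > t_end[pi]
      if (truncated) off <- t_end[pi]
      i0 <- floor(on * rate) + 1L
      i1 <- min(ceiling(off * rate), n)
      profile[i0:i1] <- params$burst_amp_uv
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        channel = channels[ci], muscle = m, side = params$side,
        kind = if (st == "stretching") "StR" else "ShR",
        phase_index = pi, t_onset = on, t_offset = off,
        latency_pct = lat_pct, truncated = truncated,
        stringsAsFactors = FALSE)
    }
    samples[, ci] <- profile * stats::rnorm(n)
  }
  truth_bursts <- do.call(rbind, truth_rows)
  if (is.null(truth_bursts)) {
    truth_bursts <- data.frame(channel = character(0), muscle = character(0),
                               side = character(0), kind = character(0),
                               phase_index = integer(0), t_onset = double(0),
                               t_offset = double(0), latency_pct = double(0),
                               truncated = logical(0))
  }
  emg <- emg_recording(samples, rate_hz = rate,
                       subject_id = sprintf("sim%04d", params$seed %% 10000L))
  list(emg = emg, phases = phases, map = map,
       truth = list(bursts = truth_bursts, params = params,
                    seed = params$seed))
}

#' Generate a synthetic EMG envelope with known bursts
#'
#' Direct envelope-level generator for validating burst detection in
#' isolation: a baseline floor with rectified-Gaussian noise and step bursts
#' of known onset, duration and amplitude, placed sequentially with a minimum
#' spacing.
#'
#' @param duration_s envelope duration (s).
#' @param rate_hz sampling rate.
#' @param baseline_uv baseline level (uV).
#' @param amp_factor_range burst amplitude range as multiples of baseline.
#' @param burst_dur_range_s burst duration range (s).
#' @param min_gap_s minimum spacing between bursts (s).
#' @param extra_gap_max_s upper bound of the uniform extra spacing (s).
#' @param noise_sd_uv envelope noise scale (uV).
#' @param margin_s quiet margin at both ends (s).
#' @param seed RNG seed.
#' @return list with `envelope` (an `envelope` object) and `truth`
#'   (data.frame `t_onset`, `t_offset`, `amp_uv`).
#' @export
generate_burst_envelope <- function(duration_s = 20, rate_hz = 1926,
                                    baseline_uv = 5,
                                    amp_factor_range = c(4, 8),
                                    burst_dur_range_s = c(0.06, 0.25),
                                    min_gap_s = 0.2, extra_gap_max_s = 0.4,
                                    noise_sd_uv = 0.8, margin_s = 1.0,
                                    seed = 1L) {
  set.seed(.derive_seed(seed, 0L))
  n <- as.integer(round(duration_s * rate_hz))
  profile <- rep(baseline_uv, n)
  t <- margin_s
  ons <- offs <- amps <- numeric(0)
  repeat {
    t <- t + min_gap_s + stats::runif(1, 0, extra_gap_max_s)
    bdur <- stats::runif(1, burst_dur_range_s[1L], burst_dur_range_s[2L])
    if (t + bdur > duration_s - margin_s) break
    amp <- baseline_uv * stats::runif(1, amp_factor_range[1L],
                                      amp_factor_range[2L])
    i0 <- floor(t * rate_hz) + 1L
    i1 <- ceiling((t + bdur) * rate_hz)
    profile[i0:i1] <- amp
    ons <- c(ons, (i0 - 1L) / rate_hz)
    offs <- c(offs, i1 / rate_hz)
    amps <- c(amps, amp)
    t <- t + bdur
  }
  values <- pmax(profile + stats::rnorm(n, 0, noise_sd_uv), 0)
  env <- structure(list(values = values, rate_hz = rate_hz, channel = NULL),
                   class = "envelope")
  list(envelope = env,
       truth = data.frame(t_onset = ons, t_offset = offs, amp_uv = amps))
}

#' Parameters for synthetic spontaneous-movement sessions
#'
#' Defaults emulate the observed spontaneous-movement statistics: about 8
#' movement units per minute of mean duration 1.2 s (SD 0.4 s) per limb over
#' a 10-minute supine recording, endpoint speed pulses peaking at 0.5 m/s
#' (2.5x the detection threshold), a 55-cm infant, 50-frame/s video and
#' 1926-Hz EMG. Antagonist EMG envelopes during movement units are lognormal
#' pairs with a target Pearson correlation `antagonist_rho`, built from a
#' Gaussian pair whose correlation is calibrated in closed form
#' (`rho_gauss = log(1 + rho*(exp(s^2)-1)) / s^2` for log-sd `s`).
#'
#' @param session_dur_s recording duration (s).
#' @param mu_rate_per_min mean movement units per minute per limb.
#' @param mu_dur_mean_s,mu_dur_sd_s,mu_dur_min_s MU duration distribution
#'   (clamped to `[mu_dur_min_s, 3]` s).
#' @param pulse_speed_mps peak endpoint speed of a movement pulse (m/s).
#' @param ramp_s rise/fall time of the trapezoidal speed pulse (s).
#' @param min_gap_s minimum gap between consecutive MUs of one limb (s).
#' @param inter_limb_overlap_prob probability that an MU is co-scheduled on
#'   another limb (ignored with a single limb).
#' @param antagonist_rho target within-MU Pearson correlation of the
#'   antagonist envelope pair, in `[-1, 1]` (very negative targets can be
#'   unreachable for lognormal pairs and raise an error).
#' @param body_height_cm infant body height.
#' @param video_rate_hz,emg_rate_hz sampling rates.
#' @param baseline_uv,burst_amp_uv,log_sd EMG envelope model: baseline floor,
#'   burst scale, and log-sd of the lognormal modulation.
#' @param xy_noise_cm tracking jitter added to trajectories (cm, SD).
#' @param limbs which limbs to simulate.
#' @param with_emg also synthesize EMG (FALSE for kinematics-only studies).
#' @param keep_profiles store the clean envelope profiles in the ground truth
#'   (memory-heavy; for validation on short sessions).
#' @param seed master RNG seed.
#' @return validated parameter list of class `spontaneous_gen_params`.
#' @export
spontaneous_gen_params <- function(session_dur_s = 600,
                                   mu_rate_per_min = 8,
                                   mu_dur_mean_s = 1.2, mu_dur_sd_s = 0.4,
                                   mu_dur_min_s = 0.2,
                                   pulse_speed_mps = 0.5, ramp_s = 0.05,
                                   min_gap_s = 0.2,
                                   inter_limb_overlap_prob = 0.7,
                                   antagonist_rho = 0.5,
                                   body_height_cm = 55,
                                   video_rate_hz = 50, emg_rate_hz = 1926,
                                   baseline_uv = 5, burst_amp_uv = 11,
                                   log_sd = 0.8, xy_noise_cm = 0.05,
                                   limbs = .LIMBS, with_emg = TRUE,
                                   keep_profiles = FALSE, seed = 1L) {
  p <- as.list(environment())
  for (f in c("session_dur_s", "mu_dur_mean_s", "mu_dur_min_s",
              "pulse_speed_mps", "body_height_cm", "video_rate_hz",
              "emg_rate_hz", "baseline_uv", "burst_amp_uv", "log_sd")) {
    if (p[[f]] <= 0) .stop_input(f, " must be positive")
  }
  if (p$mu_rate_per_min < 0) .stop_input("mu_rate_per_min must be >= 0")
  if (abs(p$antagonist_rho) > 1) .stop_input("antagonist_rho must be in [-1, 1]")
  if (p$inter_limb_overlap_prob < 0 || p$inter_limb_overlap_prob > 1) {
    .stop_input("inter_limb_overlap_prob must be in [0, 1]")
  }
  if (!all(p$limbs %in% .LIMBS)) .stop_input("unknown limb")
  if (p$mu_rate_per_min > 0) {
    slack <- 60 / p$mu_rate_per_min - p$mu_dur_mean_s - p$min_gap_s
    if (slack <= 0.05) {
      .stop_input("mu_rate_per_min too high for the gap constraint")
    }
  }
  class(p) <- c("spontaneous_gen_params", "list")
  p
}

## antagonist pair per limb: thigh pair for legs, arm pair for arms
.limb_pair <- function(limb) {
  if (grepl("leg$", limb)) c("RF", "BF") else c("BB", "TB")
}
.limb_side <- function(limb) if (grepl("^left", limb)) "L" else "R"

#' Generate a synthetic spontaneous-movement session
#'
#' Per limb, MU onsets follow a Poisson-like renewal process thinned to a
#' minimum gap; each MU is a trapezoidal endpoint speed pulse integrated to a
#' 2D path whose excursion exceeds the detection bound; with probability
#' `inter_limb_overlap_prob` an MU is co-scheduled (with onset jitter) on
#' another limb. During MUs, antagonist EMG envelopes are correlated
#' lognormal pairs at the calibrated Gaussian correlation; raw EMG is
#' profile-modulated Gaussian noise.
#'
#' @param params [spontaneous_gen_params()].
#' @return list with `trajectories` (named list of [trajectory()]), `emg`
#'   ([emg_recording()] or NULL), and `truth`: list with `mus` (data.frame
#'   `limb`, `t_onset`, `t_offset`, `duration_s`), `rho_target`,
#'   `rho_gauss`, `params`, `seed`, and `profiles` when requested.
#' @export
generate_spontaneous_session <- function(params = spontaneous_gen_params()) {
  stopifnot(inherits(params, "spontaneous_gen_params"))
  vr <- params$video_rate_hz
  nv <- as.integer(round(params$session_dur_s * vr))
  limbs <- params$limbs
  ## 1. per-limb schedules (streams 100 + i)
  sched <- list()
  for (i in seq_along(limbs)) {
    set.seed(.derive_seed(params$seed, 100L + i))
    ons <- offs <- numeric(0)
    if (params$mu_rate_per_min > 0) {
      slack <- 60 / params$mu_rate_per_min - params$mu_dur_mean_s -
        params$min_gap_s
      t <- 1.0
      repeat {
        gap <- params$min_gap_s + stats::rexp(1, 1 / slack)
        dur <- .rnorm_clamped(1, params$mu_dur_mean_s, params$mu_dur_sd_s,
                              lo = params$mu_dur_min_s, hi = 3)
        on <- t + gap
        if (on + dur > params$session_dur_s - 1.0) break
        ons <- c(ons, on); offs <- c(offs, on + dur)
        t <- on + dur
      }
    }
    sched[[limbs[i]]] <- data.frame(t_onset = ons, t_offset = offs)
  }
  ## 2. inter-limb co-scheduling (stream 99)
  if (length(limbs) > 1L && params$inter_limb_overlap_prob > 0) {
    set.seed(.derive_seed(params$seed, 99L))
    for (i in seq_along(limbs)) {
      base <- sched[[limbs[i]]]
      for (k in seq_len(nrow(base))) {
        if (stats::runif(1) >= params$inter_limb_overlap_prob) next
        target <- sample(setdiff(limbs, limbs[i]), 1L)
        jit <- stats::runif(1, -0.2, 0.2)
        on <- max(base$t_onset[k] + jit, 0.5)
        off <- on + (base$t_offset[k] - base$t_onset[k])
        if (off > params$session_dur_s - 0.5) next
        tg <- sched[[target]]
        clash <- any(tg$t_onset < off + params$min_gap_s &
                       on - params$min_gap_s < tg$t_offset)
        if (!clash) {
          tg <- rbind(tg, data.frame(t_onset = on, t_offset = off))
          sched[[target]] <- tg[order(tg$t_onset), , drop = FALSE]
        }
      }
    }
  }
  ## 3. trajectories (streams 200 + i)
  trajectories <- list()
  for (i in seq_along(limbs)) {
    set.seed(.derive_seed(params$seed, 200L + i))
    sc <- sched[[limbs[i]]]
    speed <- numeric(nv)  # m/s profile at video rate
    angle <- numeric(nrow(sc))
    for (k in seq_len(nrow(sc))) {
      dur <- sc$t_offset[k] - sc$t_onset[k]
      ramp <- min(params$ramp_s, dur / 4)
      tt <- (seq_len(nv) - 1L) / vr - sc$t_onset[k]
      inpulse <- tt >= 0 & tt < dur
      prof <- pmin(1, pmin(tt, dur - tt) / ramp)
      speed[inpulse] <- params$pulse_speed_mps * prof[inpulse]
      angle[k] <- (sample(0:3, 1L) * 90 + stats::runif(1, -20, 20)) * pi / 180
    }
    dirx <- diry <- numeric(nv)
    for (k in seq_len(nrow(sc))) {
      tt <- (seq_len(nv) - 1L) / vr - sc$t_onset[k]
      inpulse <- tt >= 0 & tt < (sc$t_offset[k] - sc$t_onset[k])
      dirx[inpulse] <- cos(angle[k]); diry[inpulse] <- sin(angle[k])
    }
    x <- cumsum(speed * dirx) * 100 / vr  # cm
    y <- cumsum(speed * diry) * 100 / vr
    x <- x + stats::rnorm(nv, 0, params$xy_noise_cm)
    y <- y + stats::rnorm(nv, 0, params$xy_noise_cm)
    trajectories[[limbs[i]]] <- trajectory(cbind(x, y), rate_hz = vr,
                                           limb = limbs[i],
                                           body_height_cm = params$body_height_cm)
  }
  ## 4. EMG with correlated antagonist envelopes
  emg <- NULL
  profiles <- NULL
  rho_gauss <- NA_real_
  if (params$with_emg) {
    s2 <- params$log_sd^2
    base_arg <- 1 + params$antagonist_rho * expm1(s2)
    if (base_arg <= 0) {
      .stop_input("antagonist_rho unreachable for lognormal envelope pairs")
    }
    rho_gauss <- log(base_arg) / s2
    er <- params$emg_rate_hz
    ne <- as.integer(round(params$session_dur_s * er))
    h <- as.integer(round(0.05 * er))  # 100-ms modulation smoothing
    k <- 2L * h + 1L
    channels <- unlist(lapply(limbs, function(l) {
      paste(.limb_pair(l), .limb_side(l), sep = "_")
    }))
    samples <- matrix(0, nrow = ne, ncol = length(channels),
                      dimnames = list(NULL, channels))
    prof_mat <- matrix(params$baseline_uv, nrow = ne,
                       ncol = length(channels),
                       dimnames = list(NULL, channels))
    for (i in seq_along(limbs)) {
      set.seed(.derive_seed(params$seed, 300L + i))  # modulation pair stream
      sc <- sched[[limbs[i]]]
      cols <- paste(.limb_pair(limbs[i]), .limb_side(limbs[i]), sep = "_")
      for (m in seq_len(nrow(sc))) {
        i0 <- ceiling(sc$t_onset[m] * er - 1e-9) + 1L
        i1 <- min(ceiling(sc$t_offset[m] * er - 1e-9), ne)
        nmu <- i1 - i0 + 1L
        zraw <- stats::rnorm(nmu + k - 1L)
        wraw <- stats::rnorm(nmu + k - 1L)
        za <- .smooth_exact(zraw, k, nmu) * sqrt(k)
        zw <- .smooth_exact(wraw, k, nmu) * sqrt(k)
        zb <- rho_gauss * za + sqrt(max(0, 1 - rho_gauss^2)) * zw
        prof_mat[i0:i1, cols[1L]] <- params$baseline_uv +
          params$burst_amp_uv * exp(params$log_sd * za)
        prof_mat[i0:i1, cols[2L]] <- params$baseline_uv +
          params$burst_amp_uv * exp(params$log_sd * zb)
      }
    }
    for (ci in seq_along(channels)) {  # carrier noise, one stream per channel
      set.seed(.derive_seed(params$seed, 400L + ci))
      samples[, ci] <- prof_mat[, ci] * stats::rnorm(ne)
    }
    emg <- emg_recording(samples, rate_hz = er,
                         subject_id = sprintf("sim%04d", params$seed %% 10000L))
    if (params$keep_profiles) profiles <- prof_mat
  }
  mus <- do.call(rbind, lapply(limbs, function(l) {
    sc <- sched[[l]]
    if (nrow(sc) == 0L) return(NULL)
    data.frame(limb = l, t_onset = sc$t_onset, t_offset = sc$t_offset,
               duration_s = sc$t_offset - sc$t_onset,
               stringsAsFactors = FALSE)
  }))
  if (is.null(mus)) {
    mus <- data.frame(limb = character(0), t_onset = double(0),
                      t_offset = double(0), duration_s = double(0))
  }
  rownames(mus) <- NULL
  list(trajectories = trajectories, emg = emg,
       truth = list(mus = mus, rho_target = params$antagonist_rho,
                    rho_gauss = rho_gauss, params = params,
                    seed = params$seed, profiles = profiles))
}
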