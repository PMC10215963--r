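#' Multi-channel surface EMG recording
#'
#' Container for a uniformly sampled, multi-channel surface EMG recording in
#' microvolts. Channels are named `<MUSCLE>_<SIDE>` where the muscle is one of
#' RF (rectus femoris), BF (biceps femoris), TA (tibialis anterior), GL
#' (gastrocnemius lateralis), BB (biceps brachii), TB (triceps brachii) and
#' the side is L or R. All channels share one time grid: sample `i` covers
#' `[(i-1)/rate_hz, i/rate_hz)` seconds from the start of the recording.
#'
#' @param samples numeric matrix (or data.frame) with one column per channel,
#'   column names `<MUSCLE>_<SIDE>`; values in microvolts.
#' @param rate_hz sampling rate in Hz (the recording system used here samples
#'   at a nominal 1926 Hz).
#' @param subject_id subject identifier.
#' @param group `"fullterm"` or `"preterm"`.
#' @param corrected_age_months non-negative age in months (corrected age for
#'   preterm infants).
#' @return An object of class `emg_recording`: a list with elements
#'   `samples` (matrix), `rate_hz`, `subject_id`, `group`,
#'   `corrected_age_months`.
#' @examples
#' x <- matrix(rnorm(2000), ncol = 2,
#'             dimnames = list(NULL, c("RF_L", "BF_L")))
#' rec <- emg_recording(x, rate_hz = 1000)
#' rec
#' @export
emg_recording <- function(samples, rate_hz, subject_id = "s01",
                          group = c("fullterm", "preterm"),
                          corrected_age_months = 0) {
  group <- match.arg(group)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(colnames(samples)) || any(!nzchar(colnames(samples)))) {
    .stop_input("EMG channels must be named <MUSCLE>_<SIDE>")
  }
  lab <- parse_channel(colnames(samples))
  if (anyDuplicated(colnames(samples))) {
    .stop_input("duplicated EMG channel: ",
                colnames(samples)[duplicated(colnames(samples))][1L])
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    .stop_input("rate_hz must be a positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    .stop_input("EMG samples contain missing or non-finite values")
  }
  if (!is.numeric(corrected_age_months) || corrected_age_months < 0) {
    .stop_input("corrected_age_months must be non-negative")
  }
  structure(list(samples = samples, rate_hz = rate_hz,
                 subject_id = as.character(subject_id), group = group,
                 corrected_age_months = corrected_age_months,
                 channels = lab),
            class = "emg_recording")
}

#' Parse channel labels of the form `<MUSCLE>_<SIDE>`
#'
#' @param x character vector of channel names such as `"RF_L"`.
#' @return data.frame with columns `channel`, `muscle`, `side`.
#' @export
parse_channel <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  muscle <- vapply(parts, `[`, "", 1L)
  side <- vapply(parts, `[`, "", 2L)
  bad <- bad | !(muscle %in% .MUSCLES) | !(side %in% .SIDES)
  if (any(bad)) .stop_input("unknown EMG channel name: ", x[bad][1L])
  data.frame(channel = x, muscle = muscle, side = side,
             stringsAsFactors = FALSE)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s (%s, %.1f mo)\n",
              x$subject_id, x$group, x$corrected_age_months))
  cat(sprintf("  %d channel(s) [%s], %d samples @ %g Hz (%.2f s)\n",
              ncol(x$samples), paste(colnames(x$samples), collapse = ", "),
              nrow(x$samples), x$rate_hz, nrow(x$samples) / x$rate_hz))
  invisible(x)
}

#' Duration of a recording or trajectory in seconds
#' @param x an `emg_recording` or `trajectory`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) UseMethod("duration_s")

#' @export
duration_s.emg_recording <- function(x) nrow(x$samples) / x$rate_hz

#' @export
duration_s.trajectory <- function(x) nrow(x$xy) / x$rate_hz

#' Passive-movement phase annotation
#'
#' Ordered flexion/extension intervals for passive movements of one joint and
#' side. Intervals are half-open `[t_start, t_end)` seconds; within each
#' (joint, side) trial phases must be strictly increasing, non-overlapping and
#' alternate in direction (the experimenter cycles flexion/extension). For the
#' ankle, "flexion" denotes dorsiflexion and "extension" plantarflexion.
#'
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`, `"elbow"` (recycled).
#' @param side `"L"` or `"R"` (recycled).
#' @param direction vector of `"flexion"`/`"extension"`.
#' @param t_start,t_end phase boundaries in seconds.
#' @return data.frame of class `phase_annotation` with an added `phase_index`
#'   (1-based within each joint-side trial).
#' @export
phase_annotation <- function(joint, side, direction, t_start, t_end) {
  df <- data.frame(joint = joint, side = side, direction = direction,
                   t_start = as.double(t_start), t_end = as.double(t_end),
                   stringsAsFactors = FALSE)
  if (!all(df$joint %in% .JOINTS)) .stop_input("unknown joint")
  if (!all(df$side %in% .SIDES)) .stop_input("side must be L or R")
  if (!all(df$direction %in% .DIRECTIONS)) {
    .stop_input("direction must be flexion or extension")
  }
  if (any(df$t_end <= df$t_start)) .stop_input("phase t_end must exceed t_start")
  df$phase_index <- NA_integer_
  for (key in unique(paste(df$joint, df$side))) {
    idx <- which(paste(df$joint, df$side) == key)
    idx <- idx[order(df$t_start[idx])]
    d <- df[idx, ]
    if (any(d$t_start[-1L] < d$t_end[-nrow(d)])) {
      .stop_input("phases overlap within a trial")
    }
    if (nrow(d) > 1L && any(d$direction[-1L] == d$direction[-nrow(d)])) {
      .stop_input("phase directions must alternate within a trial")
    }
    df$phase_index[idx] <- seq_along(idx)
  }
  df <- df[order(df$joint, df$side, df$t_start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phase_annotation", "data.frame")
  df
}

#' 2D limb-endpoint trajectory
#'
#' Endpoint (wrist or toe) position over time in the camera plane, in
#' centimeters, on a uniform grid (nominal 50 frames/s video). `valid` marks
#' samples usable for movement-unit detection; invalid spans (e.g. tracking
#' dropouts too long to interpolate) act as barriers that movement episodes
#' never cross.
#'
#' @param xy numeric matrix with columns x, y in cm.
#' @param rate_hz frame rate in Hz.
#' @param limb one of `"left_arm"`, `"right_arm"`, `"left_leg"`, `"right_leg"`.
#' @param body_height_cm infant body height in cm (used by the excursion
#'   criterion of movement-unit detection).
#' @param valid logical vector marking usable samples (default all TRUE).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(xy, rate_hz, limb, body_height_cm, valid = NULL) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L) .stop_input("xy must have two columns")
  colnames(xy) <- c("x", "y")
  if (!limb %in% .LIMBS) .stop_input("unknown limb: ", limb)
  if (!is.numeric(rate_hz) || rate_hz <= 0) .stop_input("rate_hz must be positive")
  if (!is.numeric(body_height_cm) || body_height_cm <= 0) {
    .stop_input("body_height_cm must be positive")
  }
  if (is.null(valid)) valid <- rep(TRUE, nrow(xy))
  valid <- as.logical(valid)
  if (length(valid) != nrow(xy)) .stop_input("valid must match xy length")
  if (any(!is.finite(xy[valid, ]))) {
    .stop_input("trajectory coordinates must be finite where valid")
  }
  structure(list(xy = xy, rate_hz = rate_hz, limb = limb,
                 body_height_cm = body_height_cm, valid = valid),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d frames @ %g Hz (%.2f s), height %.1f cm, %d invalid\n",
              x$limb, nrow(x$xy), x$rate_hz, nrow(x$xy) / x$rate_hz,
              x$body_height_cm, sum(!x$valid)))
  invisible(x)
}

#' Pipeline configuration with defaults
#'
#' All tunable thresholds of the analysis in one place. Defaults are the
#' constants of the analysis protocol: a 20-ms RMS envelope window; baseline
#' fragments of at least 0.5 s whose mean stays within 1.2x the trial
#' minimum; bursts exceeding twice the baseline for at least 30 ms, merged
#' when separated by less than 50 ms; responses classified when lasting more
#' than 100 ms within a phase; movement units above 0.2 m/s for more than
#' 0.2 s, merged across gaps under 0.5 s, with per-coordinate excursion of at
#' least 15% of body height (alternative set: >0.1 s, <0.3 s, >=10%); a 0.3-s
#' velocity smoothing window; and the 25% overlap bound of the separated-MU
#' rule.
#'
#' @param rms_window_s EMG RMS smoothing window (s).
#' @param baseline_min_dur_s minimum quiet-fragment duration (s).
#' @param baseline_factor quiet fragments stay within this factor of the
#'   minimum windowed mean.
#' @param burst_factor burst threshold as a multiple of the baseline level.
#' @param burst_min_dur_s minimum supra-threshold run duration (s).
#' @param burst_merge_gap_s runs closer than this are one response (s).
#' @param response_min_dur_s StR/ShR need a truncated duration above this (s).
#' @param mu_speed_threshold_mps movement-unit speed threshold (m/s).
#' @param mu_min_dur_s minimum movement-episode duration (s).
#' @param mu_merge_gap_s episodes closer than this are combined (s).
#' @param mu_excursion_frac excursion bound as a fraction of body height.
#' @param mu_speed_smooth_s velocity smoothing window (s).
#' @param separated_overlap_frac overlap bound of the separated-MU rule.
#' @param likelihood_threshold pose-tracker points below this are invalid.
#' @param max_gap_fill_s invalid tracking gaps up to this long are linearly
#'   interpolated; longer gaps are excluded from MU detection.
#' @param mu_criteria `"main"` or `"alternative"`; `"alternative"` replaces
#'   `mu_min_dur_s`, `mu_merge_gap_s`, `mu_excursion_frac` by 0.1, 0.3, 0.10.
#' @param merge_first if TRUE, merge movement episodes before the duration
#'   filter (sensitivity analysis; the default follows the listed order
#'   threshold -> duration -> merge -> excursion).
#' @param overlap_mode `"max"` compares each MU with single MUs of other limbs
#'   (default); `"union"` uses the union of other-limb MU time.
#' @param min_cycles,lock_frac rhythmic-distant-activity screen: minimum
#'   number of flexion/extension cycles, and the fraction of same-direction
#'   phases that must contain a burst.
#' @param rng_seed seed recorded in run manifests.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(rms_window_s = 0.020,
                            baseline_min_dur_s = 0.5,
                            baseline_factor = 1.2,
                            burst_factor = 2.0,
                            burst_min_dur_s = 0.030,
                            burst_merge_gap_s = 0.050,
                            response_min_dur_s = 0.100,
                            mu_speed_threshold_mps = 0.2,
                            mu_min_dur_s = 0.2,
                            mu_merge_gap_s = 0.5,
                            mu_excursion_frac = 0.15,
                            mu_speed_smooth_s = 0.3,
                            separated_overlap_frac = 0.25,
                            likelihood_threshold = 0.6,
                            max_gap_fill_s = 0.2,
                            mu_criteria = c("main", "alternative"),
                            merge_first = FALSE,
                            overlap_mode = c("max", "union"),
                            min_cycles = 3L,
                            lock_frac = 0.5,
                            rng_seed = 1L) {
  mu_criteria <- match.arg(mu_criteria)
  overlap_mode <- match.arg(overlap_mode)
  if (mu_criteria == "alternative") {
    if (missing(mu_min_dur_s)) mu_min_dur_s <- 0.1
    if (missing(mu_merge_gap_s)) mu_merge_gap_s <- 0.3
    if (missing(mu_excursion_frac)) mu_excursion_frac <- 0.10
  }
  cfg <- list(rms_window_s = rms_window_s,
              baseline_min_dur_s = baseline_min_dur_s,
              baseline_factor = baseline_factor,
              burst_factor = burst_factor,
              burst_min_dur_s = burst_min_dur_s,
              burst_merge_gap_s = burst_merge_gap_s,
              response_min_dur_s = response_min_dur_s,
              mu_speed_threshold_mps = mu_speed_threshold_mps,
              mu_min_dur_s = mu_min_dur_s,
              mu_merge_gap_s = mu_merge_gap_s,
              mu_excursion_frac = mu_excursion_frac,
              mu_speed_smooth_s = mu_speed_smooth_s,
              separated_overlap_frac = separated_overlap_frac,
              likelihood_threshold = likelihood_threshold,
              max_gap_fill_s = max_gap_fill_s,
              mu_criteria = mu_criteria,
              merge_first = isTRUE(merge_first),
              overlap_mode = overlap_mode,
              min_cycles = as.integer(min_cycles),
              lock_frac = lock_frac,
              rng_seed = as.integer(rng_seed))
  dur <- c("rms_window_s", "baseline_min_dur_s", "burst_min_dur_s",
           "burst_merge_gap_s", "response_min_dur_s", "mu_min_dur_s",
           "mu_merge_gap_s", "mu_speed_smooth_s", "mu_speed_threshold_mps",
           "baseline_factor", "burst_factor")
  for (f in dur) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      .stop_input(f, " must be positive")
    }
  }
  for (f in c("mu_excursion_frac", "separated_overlap_frac", "lock_frac")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) .stop_input(f, " must be in (0, 1]")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Keys missing from the file keep the package defaults; unknown keys are an
#' error so that typos in threshold names do not silently run with defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file of config keys.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) .stop_input("unknown config key: ", unknown[1L])
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param cfg `pipeline_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
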