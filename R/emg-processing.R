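#' Rectify and RMS-smooth a raw EMG channel
#'
#' Computes the EMG envelope: the raw signal is rectified and smoothed with a
#' sliding 20-ms window using root-mean-square averaging. The window is
#' centered on each sample and shrinks at the edges (no zero padding, which
#' would create artificial onset dips).
#'
#' @param raw numeric vector, raw EMG in microvolts.
#' @param rate_hz sampling rate in Hz.
#' @param rms_window_s window length in seconds (default 0.020).
#' @return object of class `envelope`: list with `values` (non-negative
#'   microvolt series), `rate_hz`, and the source `channel` name if known.
#' @examples
#' env <- rectify_and_smooth(rnorm(2000, sd = 5), rate_hz = 1926)
#' range(env$values)
#' @export
rectify_and_smooth <- function(raw, rate_hz, rms_window_s = 0.020) {
  if (length(raw) == 0L) .stop_input("empty EMG series")
  half <- floor(rate_hz * rms_window_s / 2)
  n <- length(raw)
  cs <- cumsum(c(0, as.double(raw)^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  vals <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  structure(list(values = vals, rate_hz = rate_hz,
                 channel = attr(raw, "channel")),
            class = "envelope")
}

#' Compute envelopes for every channel of a recording
#' @param rec [emg_recording()].
#' @param rms_window_s RMS window in seconds.
#' @return named list of `envelope` objects, one per channel.
#' @export
envelopes <- function(rec, rms_window_s = 0.020) {
  stopifnot(inherits(rec, "emg_recording"))
  out <- lapply(colnames(rec$samples), function(ch) {
    e <- rectify_and_smooth(rec$samples[, ch], rec$rate_hz, rms_window_s)
    e$channel <- ch
    e
  })
  names(out) <- colnames(rec$samples)
  out
}

#' Wrap a precomputed envelope series
#'
#' Constructs an `envelope` object from an already rectified-and-smoothed
#' non-negative series (e.g. simulated envelopes or data preprocessed
#' elsewhere).
#'
#' @param values non-negative numeric series (microvolts).
#' @param rate_hz sampling rate in Hz.
#' @param channel optional channel label.
#' @return `envelope` object.
#' @export
as_envelope <- function(values, rate_hz, channel = NULL) {
  if (any(values < 0)) .stop_input("envelope values must be non-negative")
  if (!is.numeric(rate_hz) || rate_hz <= 0) .stop_input("rate_hz must be positive")
  structure(list(values = as.double(values), rate_hz = rate_hz,
                 channel = channel), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope>%s %d samples @ %g Hz, mean %.2f uV\n",
              if (is.null(x$channel)) "" else paste0(" ", x$channel),
              length(x$values), x$rate_hz, mean(x$values)))
  invisible(x)
}

#' Estimate the per-muscle baseline activity level
#'
#' Identifies quiet (baseline) fragments: intervals of at least
#' `baseline_min_dur_s` whose windowed mean envelope stays within
#' `baseline_factor` times the minimum level of the trial. The "minimum level"
#' is the smallest mean over all sliding windows of `baseline_min_dur_s` —
#' never a single-sample minimum, which would be noise-dominated. The baseline
#' level is the mean envelope over the union of qualifying fragments.
#'
#' @param env `envelope` object (or numeric vector with a `rate_hz` attr).
#' @param baseline_min_dur_s minimum quiet-fragment duration in seconds.
#' @param baseline_factor tolerance factor over the minimum windowed mean.
#' @return object of class `baseline_estimate`: list with `level_uv`,
#'   `floor_uv` and `segments` (data.frame `t_start`, `t_end` of qualifying
#'   intervals, half-open, seconds).
#' @export
estimate_baseline <- function(env, baseline_min_dur_s = 0.5,
                              baseline_factor = 1.2) {
  stopifnot(inherits(env, "envelope"))
  x <- env$values
  w <- as.integer(round(env$rate_hz * baseline_min_dur_s))
  if (w < 1L || w > length(x)) {
    .stop_input("recording shorter than the baseline window")
  }
  wm <- .roll_mean_width(x, w)
  floor_uv <- min(wm)
  ## small relative tolerance so the minimizing window itself always
  ## qualifies despite floating-point summation order
  thr <- baseline_factor * floor_uv * (1 + 1e-12)
  ok <- wm <= thr
  ## union of qualifying windows [j, j + w - 1]
  n <- length(x)
  starts <- which(ok)
  delta <- tabulate(starts, nbins = n) - tabulate(starts + w, nbins = n)
  covered <- cumsum(delta) > 0L
  segs <- .logical_runs(covered)
  level_uv <- mean(x[covered])
  structure(list(level_uv = level_uv, floor_uv = floor_uv,
                 segments = data.frame(
                   t_start = (segs[, 1L] - 1L) / env$rate_hz,
                   t_end = segs[, 2L] / env$rate_hz)),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> level %.2f uV (floor %.2f uV), %d segment(s), %.2f s quiet\n",
              x$level_uv, x$floor_uv, nrow(x$segments),
              sum(x$segments$t_end - x$segments$t_start)))
  invisible(x)
}

#' Detect EMG bursts against a baseline level
#'
#' Finds periods of EMG activity exceeding the baseline level at least
#' `burst_factor` times (strictly) for at least `burst_min_dur_s`; runs
#' separated by less than `burst_merge_gap_s` are combined into a single
#' muscle response. The minimum-duration filter is applied to raw
#' supra-threshold runs first, then merging proceeds to a fixed point.
#'
#' @param env `envelope` object.
#' @param base `baseline_estimate` for the same channel, or a bare numeric
#'   baseline level in microvolts.
#' @param burst_factor threshold multiple of the baseline level (default 2).
#' @param burst_min_dur_s minimum run duration in seconds (default 0.030).
#' @param burst_merge_gap_s merge gap in seconds (default 0.050).
#' @return data.frame with one row per burst: `t_onset`, `t_offset`,
#'   `duration_s`, `mean_amp_uv` (mean envelope over the burst),
#'   `baseline_uv`, plus `channel` when the envelope carries one.
#' @export
detect_bursts <- function(env, base, burst_factor = 2.0,
                          burst_min_dur_s = 0.030,
                          burst_merge_gap_s = 0.050) {
  stopifnot(inherits(env, "envelope"))
  if (is.numeric(base)) {
    base <- structure(list(level_uv = as.double(base), floor_uv = base,
                           segments = NULL), class = "baseline_estimate")
  }
  stopifnot(inherits(base, "baseline_estimate"))
  if (base$level_uv < 0) .stop_input("baseline level must be non-negative")
  rate <- env$rate_hz
  thr <- burst_factor * base$level_uv
  runs <- .logical_runs(env$values > thr)
  ## keep runs lasting at least burst_min_dur_s (run of k samples = k/rate s)
  min_len <- burst_min_dur_s * rate - 1e-9
  runs <- runs[(runs[, 2L] - runs[, 1L] + 1L) >= min_len, , drop = FALSE]
  ## merge runs separated by gaps shorter than burst_merge_gap_s
  max_gap <- burst_merge_gap_s * rate - 1e-9  # gap of k samples = k/rate s
  runs <- .merge_runs(runs, max_gap)
  k <- nrow(runs)
  amp <- vapply(seq_len(k), function(i) {
    mean(env$values[runs[i, 1L]:runs[i, 2L]])
  }, 0)
  out <- data.frame(t_onset = (runs[, 1L] - 1L) / rate,
                    t_offset = runs[, 2L] / rate,
                    duration_s = (runs[, 2L] - runs[, 1L] + 1L) / rate,
                    mean_amp_uv = amp,
                    baseline_uv = rep(base$level_uv, k))
  if (!is.null(env$channel)) {
    out <- cbind(channel = rep(env$channel, k), out,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Detect bursts on every channel of a recording
#'
#' Convenience wrapper: envelope, baseline and burst detection per channel,
#' returning one tidy table ready for response classification.
#'
#' @param rec [emg_recording()].
#' @param cfg [pipeline_config()].
#' @return data.frame with columns `subject`, `channel`, `muscle`, `side`,
#'   `t_onset`, `t_offset`, `duration_s`, `mean_amp_uv`, `baseline_uv`.
#' @export
detect_session_bursts <- function(rec, cfg = pipeline_config()) {
  env <- envelopes(rec, cfg$rms_window_s)
  res <- lapply(env, function(e) {
    base <- estimate_baseline(e, cfg$baseline_min_dur_s, cfg$baseline_factor)
    detect_bursts(e, base, cfg$burst_factor, cfg$burst_min_dur_s,
                  cfg$burst_merge_gap_s)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(channel = character(0), t_onset = double(0),
                      t_offset = double(0), duration_s = double(0),
                      mean_amp_uv = double(0), baseline_uv = double(0))
  }
  lab <- parse_channel(out$channel)
  cbind(subject = rep(rec$subject_id, nrow(out)),
        out[, "channel", drop = FALSE],
        muscle = lab$muscle, side = lab$side,
        out[, setdiff(names(out), "channel"), drop = FALSE])
}
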