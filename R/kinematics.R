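#' Smoothed 2D endpoint speed
#'
#' Instantaneous 2D velocity by central finite differences (forward/backward
#' at the edges), converted from cm to m, then smoothed with a centered
#' moving-average window of `smooth_window_s` (0.3 s by default; edge windows
#' shrink).
#'
#' @param traj [trajectory()].
#' @param smooth_window_s smoothing window in seconds.
#' @return numeric vector of non-negative speeds in m/s, aligned to the
#'   trajectory samples.
#' @export
compute_speed <- function(traj, smooth_window_s = 0.3) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$xy)
  if (n < 2L) .stop_input("trajectory too short for velocities")
  rate <- traj$rate_hz
  vx <- vy <- numeric(n)
  x <- traj$xy[, 1L]; y <- traj$xy[, 2L]
  i <- 2:(n - 1L)
  vx[i] <- (x[i + 1L] - x[i - 1L]) * rate / 2
  vy[i] <- (y[i + 1L] - y[i - 1L]) * rate / 2
  vx[1L] <- (x[2L] - x[1L]) * rate; vy[1L] <- (y[2L] - y[1L]) * rate
  vx[n] <- (x[n] - x[n - 1L]) * rate; vy[n] <- (y[n] - y[n - 1L]) * rate
  speed <- sqrt(vx^2 + vy^2) / 100  # cm/s -> m/s
  half <- floor(rate * smooth_window_s / 2)
  .roll_mean_center(speed, half)
}

#' Segment movement units from an endpoint trajectory
#'
#' Movement units (MUs) are episodes of prominent endpoint motion: the
#' smoothed 2D speed exceeds `mu_speed_threshold_mps` (strictly) for more
#' than `mu_min_dur_s`; episodes separated by less than `mu_merge_gap_s` are
#' combined (to a fixed point); and the endpoint excursion (max minus min
#' within the final episode) must reach `mu_excursion_frac` of body height in
#' at least one of the two coordinates. The default order is threshold ->
#' duration filter -> merge -> excursion; `cfg$merge_first` swaps the first
#' two filters for sensitivity analysis. Invalid trajectory spans act as
#' barriers: supra-threshold runs never cross them, and episodes are not
#' merged across them.
#'
#' @param traj [trajectory()].
#' @param speed speed series from [compute_speed()] (computed if NULL).
#' @param cfg [pipeline_config()]; use
#'   `pipeline_config(mu_criteria = "alternative")` for the weaker threshold
#'   set (>0.1 s, <0.3 s merge, >=10% excursion).
#' @return data.frame with one MU per row: `limb`, `t_onset`, `t_offset`,
#'   `duration_s`, `peak_speed_mps`, `excursion_x_cm`, `excursion_y_cm`.
#' @export
detect_mus <- function(traj, speed = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(speed)) speed <- compute_speed(traj, cfg$mu_speed_smooth_s)
  if (length(speed) != nrow(traj$xy)) {
    .stop_input("speed series not aligned to trajectory")
  }
  rate <- traj$rate_hz
  above <- speed > cfg$mu_speed_threshold_mps & traj$valid
  runs <- .logical_runs(above)
  min_len <- cfg$mu_min_dur_s * rate + 1e-9   # strict: duration > mu_min_dur_s
  max_gap <- cfg$mu_merge_gap_s * rate - 1e-9 # strict: gap < mu_merge_gap_s
  keep_long <- function(r) {
    r[(r[, 2L] - r[, 1L] + 1L) > min_len, , drop = FALSE]
  }
  merge_valid <- function(r) {
    ## merge only across gaps free of invalid samples (barriers)
    if (nrow(r) <= 1L) return(r)
    bad <- cumsum(c(0L, !traj$valid))
    repeat {
      k <- nrow(r)
      gaps <- r[-1L, 1L] - r[-k, 2L] - 1L
      gap_bad <- bad[r[-1L, 1L]] - bad[r[-k, 2L] + 1L]  # invalid count in gap
      mergeable <- gaps <= max_gap & gap_bad == 0L
      if (!any(mergeable)) break
      grp <- cumsum(c(TRUE, !mergeable))
      r <- cbind(start = as.integer(tapply(r[, 1L], grp, min)),
                 end = as.integer(tapply(r[, 2L], grp, max)))
    }
    r
  }
  runs <- if (cfg$merge_first) keep_long(merge_valid(runs)) else
    merge_valid(keep_long(runs))
  ## excursion and peak speed on the final merged interval
  exc_thr <- cfg$mu_excursion_frac * traj$body_height_cm
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs[i, 1L]; e <- runs[i, 2L]
    ex <- diff(range(traj$xy[s:e, 1L]))
    ey <- diff(range(traj$xy[s:e, 2L]))
    if (ex < exc_thr && ey < exc_thr) return(NULL)
    data.frame(limb = traj$limb, t_onset = (s - 1L) / rate,
               t_offset = e / rate, duration_s = (e - s + 1L) / rate,
               peak_speed_mps = max(speed[s:e]),
               excursion_x_cm = ex, excursion_y_cm = ey,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(limb = character(0), t_onset = double(0),
                      t_offset = double(0), duration_s = double(0),
                      peak_speed_mps = double(0), excursion_x_cm = double(0),
                      excursion_y_cm = double(0))
  }
  rownames(out) <- NULL
  out
}

#' Flag movement units as 'separated' from other limbs' movement
#'
#' An MU is relatively separated when its temporal overlap with the movement
#' of the other limbs is below `separated_overlap_frac` of its own duration.
#' By default the overlap is the maximum intersection with any single MU of
#' another limb; `overlap_mode = "union"` instead measures the overlap with
#' the union of other-limb MU time.
#'
#' @param mus data.frame of MUs across limbs (as from [detect_mus()], rows
#'   from several limbs bound together).
#' @param separated_overlap_frac overlap bound (default 0.25).
#' @param overlap_mode `"max"` or `"union"`.
#' @return `mus` with added columns `overlap_s` and `separated` (logical).
#' @export
classify_separated <- function(mus, separated_overlap_frac = 0.25,
                               overlap_mode = c("max", "union")) {
  overlap_mode <- match.arg(overlap_mode)
  n <- nrow(mus)
  overlap <- numeric(n)
  for (i in seq_len(n)) {
    other <- mus[mus$limb != mus$limb[i], , drop = FALSE]
    if (nrow(other) == 0L) next
    ov <- .interval_overlap(mus$t_onset[i], mus$t_offset[i],
                            other$t_onset, other$t_offset)
    overlap[i] <- if (overlap_mode == "max") max(ov) else {
      ## union overlap: other-limb MUs may themselves overlap in time
      ev <- sort(unique(c(pmax(other$t_onset, mus$t_onset[i]),
                          pmin(other$t_offset, mus$t_offset[i]))))
      if (length(ev) < 2L) 0 else {
        mid <- (ev[-1L] + ev[-length(ev)]) / 2
        inside <- vapply(mid, function(m) {
          any(other$t_onset <= m & m < other$t_offset)
        }, logical(1))
        sum((ev[-1L] - ev[-length(ev)])[inside])
      }
    }
  }
  mus$overlap_s <- overlap
  mus$separated <- overlap < separated_overlap_frac * mus$duration_s
  mus
}

#' Per-limb-class MU frequency and duration
#'
#' Frequency (MU/min) and mean duration per limb, then averaged over the left
#' and right sides within each limb class (arm, leg).
#'
#' @param mus data.frame of MUs across limbs.
#' @param session_duration_s recording duration in seconds.
#' @param average_sides average left/right per limb class (default TRUE).
#' @return data.frame with `limb_class` (or `limb`), `n_mus`,
#'   `freq_per_min`, `mean_duration_s`.
#' @export
summarize_mus <- function(mus, session_duration_s, average_sides = TRUE) {
  if (!is.numeric(session_duration_s) || session_duration_s <= 0) {
    .stop_input("session_duration_s must be positive")
  }
  per_limb <- lapply(.LIMBS, function(l) {
    m <- mus[mus$limb == l, , drop = FALSE]
    data.frame(limb = l, n_mus = nrow(m),
               freq_per_min = 60 * nrow(m) / session_duration_s,
               mean_duration_s = if (nrow(m)) mean(m$duration_s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_limb <- do.call(rbind, per_limb)
  per_limb <- per_limb[per_limb$limb %in% unique(mus$limb) |
                         per_limb$n_mus > 0, , drop = FALSE]
  if (!average_sides) return(per_limb)
  per_limb$limb_class <- sub("^(left|right)_", "", per_limb$limb)
  out <- lapply(unique(per_limb$limb_class), function(cl) {
    d <- per_limb[per_limb$limb_class == cl, ]
    data.frame(limb_class = cl, n_mus = sum(d$n_mus),
               freq_per_min = mean(d$freq_per_min),
               mean_duration_s = mean(d$mean_duration_s, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
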