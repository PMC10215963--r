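## File formats. EMG and trajectories travel as CSV with `# key: value`
## metadata header lines; phase annotations and stretch maps as JSON. Writers
## emit full-precision numbers so that every reader/writer pair round-trips
## bit-identically.

.read_meta_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  meta
}

#' Read a multi-channel EMG recording from CSV
#'
#' Expects a `sample` index column plus one numeric column per channel named
#' `<MUSCLE>_<SIDE>` (values in microvolts), preceded by `# key: value`
#' comment lines carrying `rate_hz`, `subject_id`, `group` and
#' `corrected_age_months`. Arguments override header metadata.
#'
#' @param path CSV path (as written by [write_emg()]).
#' @param rate_hz,subject_id,group,corrected_age_months optional overrides of
#'   the file header metadata.
#' @return validated [emg_recording()].
#' @export
read_emg <- function(path, rate_hz = NULL, subject_id = NULL, group = NULL,
                     corrected_age_months = NULL) {
  meta <- .read_meta_header(path)
  df <- .read_table(path)
  if (!"sample" %in% names(df)) .stop_input("EMG file lacks a 'sample' column")
  chan <- setdiff(names(df), "sample")
  if (!length(chan)) .stop_input("EMG file has no channel columns")
  if (anyNA(df[chan])) .stop_input("malformed EMG file: unequal column lengths")
  rate_hz <- rate_hz %||% as.numeric(meta$rate_hz)
  if (!length(rate_hz) || is.na(rate_hz)) .stop_input("rate_hz missing")
  emg_recording(as.matrix(df[chan]), rate_hz = rate_hz,
                subject_id = subject_id %||% meta$subject_id %||% "s01",
                group = group %||% meta$group %||% "fullterm",
                corrected_age_months = corrected_age_months %||%
                  as.numeric(meta$corrected_age_months %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an EMG recording to CSV
#' @param rec [emg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emg <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", rec$subject_id),
               sprintf("# group: %s", rec$group),
               sprintf("# corrected_age_months: %s",
                       .format_full(rec$corrected_age_months)),
               sprintf("# rate_hz: %s", .format_full(rec$rate_hz))), con)
  df <- data.frame(sample = seq_len(nrow(rec$samples)) - 1L)
  for (ch in colnames(rec$samples)) df[[ch]] <- rec$samples[, ch]
  cols <- lapply(df, .format_full)
  writeLines(c(paste(names(df), collapse = ","),
               do.call(paste, c(unname(cols), sep = ","))), con)
  invisible(path)
}

#' Read a 2D endpoint trajectory
#'
#' Two dialects are supported. `"plain"` is the package's own format: comment
#' header (`limb`, `rate_hz`, `body_height_cm`) plus columns `x_cm`, `y_cm`
#' and an optional logical `valid`. `"pose_tracker"` is the CSV export of
#' markerless pose trackers: three header rows (scorer, bodyparts, coords)
#' over `x`/`y`/`likelihood` columns per bodypart, with a leading frame-index
#' column; pixel coordinates are converted to cm via `scale_cm_per_px`.
#'
#' Pose-tracker points with likelihood below `likelihood_threshold` are marked
#' invalid; invalid gaps no longer than `max_gap_fill_s` are linearly
#' interpolated, longer gaps (and invalid leading/trailing spans) stay
#' excluded from movement-unit detection.
#'
#' @param path CSV path.
#' @param dialect `"plain"` or `"pose_tracker"`.
#' @param scale_cm_per_px cm per pixel (pose_tracker dialect).
#' @param body_height_cm infant body height in cm (required for
#'   pose_tracker; header default for plain).
#' @param limb limb label (header default for plain).
#' @param bodypart which tracked bodypart to read (default: the first).
#' @param rate_hz frame rate, default 50.
#' @param likelihood_threshold,max_gap_fill_s gap policy, see above.
#' @return [trajectory()].
#' @export
read_trajectory <- function(path, dialect = c("plain", "pose_tracker"),
                            scale_cm_per_px = NULL, body_height_cm = NULL,
                            limb = NULL, bodypart = NULL, rate_hz = 50,
                            likelihood_threshold = 0.6, max_gap_fill_s = 0.2) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    meta <- .read_meta_header(path)
    df <- .read_table(path)
    if (!all(c("x_cm", "y_cm") %in% names(df))) {
      .stop_input("plain trajectory file needs x_cm and y_cm columns")
    }
    valid <- if ("valid" %in% names(df)) as.logical(df$valid) else NULL
    return(trajectory(cbind(df$x_cm, df$y_cm),
                      rate_hz = as.numeric(meta$rate_hz %||% rate_hz),
                      limb = limb %||% meta$limb %||% "left_leg",
                      body_height_cm = body_height_cm %||%
                        as.numeric(meta$body_height_cm),
                      valid = valid))
  }
  if (is.null(scale_cm_per_px) || is.null(body_height_cm)) {
    .stop_input("pose_tracker dialect needs scale_cm_per_px and body_height_cm")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) .stop_input("pose_tracker file too short")
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1L]])
  parts <- hdr[[2L]][-1L]
  coords <- hdr[[3L]][-1L]
  if (!all(c("x", "y", "likelihood") %in% coords)) {
    .stop_input("pose_tracker file lacks x/y/likelihood coords columns")
  }
  bodypart <- bodypart %||% parts[1L]
  xi <- which(parts == bodypart & coords == "x")
  yi <- which(parts == bodypart & coords == "y")
  li <- which(parts == bodypart & coords == "likelihood")
  if (length(xi) != 1L || length(yi) != 1L) {
    .stop_input("missing coords columns for bodypart: ", bodypart)
  }
  dat <- utils::read.csv(text = lines[-(1:3)], header = FALSE)
  frame <- dat[[1L]]
  if (is.unsorted(frame, strictly = TRUE)) {
    .stop_input("malformed pose_tracker file: non-monotone frame index")
  }
  x <- dat[[xi + 1L]] * scale_cm_per_px
  y <- dat[[yi + 1L]] * scale_cm_per_px
  lik <- if (length(li) == 1L) dat[[li + 1L]] else rep(1, length(x))
  ok <- is.finite(x) & is.finite(y) & lik >= likelihood_threshold
  filled <- .fill_gaps(cbind(x, y), ok, rate_hz, max_gap_fill_s)
  trajectory(filled$xy, rate_hz = rate_hz,
             limb = limb %||% "left_leg",
             body_height_cm = body_height_cm, valid = filled$valid)
}

## Linear interpolation of short invalid gaps; long gaps stay invalid and
## their coordinates are held at the nearest valid value (so that geometry is
## finite) but remain excluded via `valid`.
.fill_gaps <- function(xy, ok, rate_hz, max_gap_fill_s) {
  n <- nrow(xy)
  valid <- ok
  if (all(ok) || !any(ok)) {
    if (!any(ok)) .stop_input("no valid tracked points")
    return(list(xy = xy, valid = valid))
  }
  idx <- seq_len(n)
  for (j in 1:2) {
    xy[, j] <- stats::approx(idx[ok], xy[ok, j], xout = idx, rule = 2)$y
  }
  gaps <- .logical_runs(!ok)
  max_fill <- max_gap_fill_s * rate_hz
  for (g in seq_len(nrow(gaps))) {
    len <- gaps[g, 2L] - gaps[g, 1L] + 1L
    interior <- gaps[g, 1L] > 1L && gaps[g, 2L] < n
    if (interior && len <= max_fill) {
      valid[gaps[g, 1L]:gaps[g, 2L]] <- TRUE
    }
  }
  list(xy = xy, valid = valid)
}

#' Write a trajectory to plain-dialect CSV
#' @param traj [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# limb: %s", traj$limb),
               sprintf("# rate_hz: %s", .format_full(traj$rate_hz)),
               sprintf("# body_height_cm: %s",
                       .format_full(traj$body_height_cm))), con)
  df <- data.frame(x_cm = traj$xy[, 1L], y_cm = traj$xy[, 2L],
                   valid = traj$valid)
  cols <- lapply(df, .format_full)
  writeLines(c(paste(names(df), collapse = ","),
               do.call(paste, c(unname(cols), sep = ","))), con)
  invisible(path)
}

#' Read or write phase annotations as JSON
#'
#' @param path JSON path; an array of records with fields `joint`, `side`,
#'   `direction`, `t_start`, `t_end`.
#' @return [phase_annotation()] for the reader; `path` for the writer.
#' @export
read_phases <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  phase_annotation(df$joint, df$side, df$direction, df$t_start, df$t_end)
}

#' @rdname read_phases
#' @param phases [phase_annotation()].
#' @export
write_phases <- function(phases, path) {
  df <- as.data.frame(phases)[c("joint", "side", "direction",
                                "t_start", "t_end")]
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' Read or write a stretch map as JSON
#'
#' @param path JSON path; an array of records with fields `joint`,
#'   `direction`, `muscle`, `state`.
#' @return stretch-map data.frame for the reader; `path` for the writer.
#' @export
read_stretch_map <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  stretch_map(df$joint, df$direction, df$muscle, df$state)
}

#' @rdname read_stretch_map
#' @param map stretch map as returned by [default_stretch_map()].
#' @export
write_stretch_map <- function(map, path) {
  jsonlite::write_json(as.data.frame(map), path, digits = NA)
  invisible(path)
}
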