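# Independent brute-force oracles. These deliberately re-derive each rule
# with a different algorithm (per-sample scans, rle run lists, explicit
# loops) so that agreement with the package's vectorized implementations is
# informative.

# windowed RMS by direct per-sample summation
oracle_rms <- function(raw, rate, win_s) {
  half <- floor(rate * win_s / 2)
  n <- length(raw)
  vapply(seq_len(n), function(i) {
    w <- raw[max(1, i - half):min(n, i + half)]
    sqrt(sum(w^2) / length(w))
  }, 0)
}

# baseline by exhaustive scan over every window of exactly w samples
oracle_baseline <- function(env_values, rate, min_dur_s = 0.5, factor = 1.2) {
  n <- length(env_values)
  w <- as.integer(round(rate * min_dur_s))
  means <- vapply(seq_len(n - w + 1L), function(j) {
    mean(env_values[j:(j + w - 1L)])
  }, 0)
  floor_uv <- min(means)
  covered <- rep(FALSE, n)
  for (j in which(means <= factor * floor_uv * (1 + 1e-12))) {
    covered[j:(j + w - 1L)] <- TRUE
  }
  list(floor_uv = floor_uv, level_uv = mean(env_values[covered]),
       covered = covered)
}

# keep-then-merge on a boolean supra-threshold pattern, rle + explicit merge
# loop; returns matrix of (start, end) sample indices (1-based, inclusive)
oracle_keep_merge <- function(pat, min_len, max_gap) {
  r <- rle(as.logical(pat))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  s <- starts[keep]
  e <- ends[keep]
  i <- 1L
  while (i < length(s)) {
    if (s[i + 1L] - e[i] - 1L <= max_gap) {
      e[i] <- e[i + 1L]
      s <- s[-(i + 1L)]
      e <- e[-(i + 1L)]
    } else i <- i + 1L
  }
  cbind(start = s, end = e)
}

# full movement-unit chain (threshold -> duration -> merge -> excursion) by
# per-sample state scan on a trajectory of <= a few hundred samples
oracle_mus <- function(xy, speed, valid, rate, body_height_cm,
                       thr = 0.2, min_dur = 0.2, merge_gap = 0.5,
                       exc_frac = 0.15) {
  n <- length(speed)
  above <- speed > thr & valid
  runs <- list()
  cur <- NULL
  for (i in seq_len(n)) {
    if (above[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) (r[2] - r[1] + 1) / rate > min_dur, runs)
  # merge loop; gaps containing invalid samples are barriers
  changed <- TRUE
  while (changed && length(runs) > 1L) {
    changed <- FALSE
    for (i in seq_len(length(runs) - 1L)) {
      gap_idx <- if (runs[[i]][2] + 1 <= runs[[i + 1]][1] - 1) {
        (runs[[i]][2] + 1):(runs[[i + 1]][1] - 1)
      } else integer(0)
      gap_s <- length(gap_idx) / rate
      if (gap_s < merge_gap && all(valid[gap_idx])) {
        runs[[i]] <- c(runs[[i]][1], runs[[i + 1]][2])
        runs[[i + 1]] <- NULL
        changed <- TRUE
        break
      }
    }
  }
  keep <- Filter(function(r) {
    ex <- max(xy[r[1]:r[2], 1]) - min(xy[r[1]:r[2], 1])
    ey <- max(xy[r[1]:r[2], 2]) - min(xy[r[1]:r[2], 2])
    ex >= exc_frac * body_height_cm || ey >= exc_frac * body_height_cm
  }, runs)
  if (!length(keep)) return(cbind(start = integer(0), end = integer(0)))
  do.call(rbind, lapply(keep, function(r) cbind(start = r[1], end = r[2])))
}

# coactivation index by explicit per-sample evaluation of the printed rule
oracle_ci <- function(a, b) {
  terms <- numeric(length(a))
  for (j in seq_along(a)) {
    h <- max(a[j], b[j])
    l <- min(a[j], b[j])
    terms[j] <- if (h == 0) 0 else ((h + l) / 2) * (l / h)
  }
  mean(terms)
}

# temporal Jaccard of two half-open intervals
jaccard <- function(on1, off1, on2, off2) {
  int <- max(0, min(off1, off2) - max(on1, on2))
  uni <- max(off1, off2) - min(on1, on2)
  int / uni
}

# quick builders
make_env <- function(values, rate = 100) as_envelope(values, rate)

# piecewise envelope in sample units: list of (value, n_samples)
piecewise <- function(...) {
  segs <- list(...)
  unlist(lapply(segs, function(s) rep(s[1], s[2])))
}
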