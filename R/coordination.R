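#' Restrict a pair of envelopes to a movement unit
#'
#' Both envelope series are cut to the half-open MU interval
#' `[t_onset, t_offset)`; sample `i` belongs to the window when
#' `t_onset <= (i-1)/rate < t_offset`.
#'
#' @param envA,envB `envelope` objects sharing one rate and covering the MU.
#' @param mu single-row MU (needs `t_onset`, `t_offset`), e.g. one row of
#'   [detect_mus()] output.
#' @return list with numeric vectors `a`, `b` (equal length >= 2) and
#'   `n_samples`.
#' @export
window_envelopes <- function(envA, envB, mu) {
  stopifnot(inherits(envA, "envelope"), inherits(envB, "envelope"))
  if (envA$rate_hz != envB$rate_hz) .stop_input("envelope rates differ")
  rate <- envA$rate_hz
  i0 <- ceiling(mu$t_onset * rate - 1e-9) + 1L      # first sample in window
  i1 <- ceiling(mu$t_offset * rate - 1e-9)          # last sample in window
  if (i0 < 1L || i1 > length(envA$values) || i1 > length(envB$values)) {
    .stop_input("movement unit extends beyond the envelope span")
  }
  if (i1 - i0 + 1L < 2L) .stop_input("movement unit shorter than two samples")
  list(a = envA$values[i0:i1], b = envB$values[i0:i1],
       n_samples = i1 - i0 + 1L)
}

#' Pearson correlation of paired antagonist envelopes
#'
#' Linear correlation of the two envelope series over one MU window. When
#' either series has zero variance the correlation is undefined and `NA` is
#' returned (not 0), so that degenerate windows are excluded from averages
#' rather than biasing them toward zero.
#'
#' @param pair list from [window_envelopes()] (or any list with `a`, `b`).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
antagonist_correlation <- function(pair) {
  a <- pair$a; b <- pair$b
  if (length(a) != length(b) || length(a) < 2L) {
    .stop_input("paired series must have equal length >= 2")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Coactivation index of an antagonist muscle pair
#'
#' At each sample j, with H_j the higher and L_j the lower of the two
#' envelope values, the per-sample term is ((H_j + L_j) / 2) * (L_j / H_j)
#' (defined as 0 when H_j = 0, the limit for L -> 0), and the index is the
#' mean term over the N samples of the MU. High values indicate simultaneous
#' activation of both muscles; low values indicate rest or reciprocal
#' activation. The index is symmetric in the two muscles and bounded by
#' mean(L)/2 <= CI <= mean(L).
#'
#' @param pair list with non-negative numeric vectors `a`, `b` of equal
#'   length.
#' @return coactivation index in microvolts (non-negative).
#' @examples
#' coactivation_index(list(a = c(10, 5), b = c(8, 2)))  # 2.5
#' @export
coactivation_index <- function(pair) {
  a <- pair$a; b <- pair$b
  if (length(a) != length(b) || length(a) < 1L) {
    .stop_input("paired series must have equal length >= 1")
  }
  if (any(a < 0) || any(b < 0)) {
    .stop_input("envelopes must be non-negative")
  }
  h <- pmax(a, b)
  l <- pmin(a, b)
  term <- ifelse(h == 0, 0, ((h + l) / 2) * (l / h))
  mean(term)
}

#' Per-MU coordination metrics for an antagonist pair
#'
#' Computes the within-MU Pearson correlation and coactivation index for one
#' antagonist pair (RF-BF, TA-GL or BB-TB) on one side, for every MU of the
#' corresponding limb, from a recording's envelopes at the full EMG rate.
#'
#' @param rec [emg_recording()] containing both channels of the pair.
#' @param mus data.frame of MUs (rows with `t_onset`, `t_offset`; typically
#'   the MUs of the limb carrying the pair).
#' @param pair one of `"RF-BF"`, `"TA-GL"`, `"BB-TB"`.
#' @param side `"L"` or `"R"`.
#' @param rms_window_s envelope window (s).
#' @return data.frame with `subject`, `pair`, `side`, `t_onset`, `t_offset`,
#'   `r`, `ci_uv`, `n_samples`.
#' @export
mu_coordination <- function(rec, mus, pair = c("RF-BF", "TA-GL", "BB-TB"),
                            side = c("L", "R"), rms_window_s = 0.020) {
  pair <- match.arg(pair)
  side <- match.arg(side)
  muscles <- strsplit(pair, "-", fixed = TRUE)[[1L]]
  chans <- paste(muscles, side, sep = "_")
  if (!all(chans %in% colnames(rec$samples))) {
    .stop_input("recording lacks channels ", paste(chans, collapse = ", "))
  }
  envA <- rectify_and_smooth(rec$samples[, chans[1L]], rec$rate_hz,
                             rms_window_s)
  envB <- rectify_and_smooth(rec$samples[, chans[2L]], rec$rate_hz,
                             rms_window_s)
  envA$rate_hz <- envB$rate_hz <- rec$rate_hz
  rows <- lapply(seq_len(nrow(mus)), function(i) {
    w <- window_envelopes(envA, envB, mus[i, ])
    data.frame(subject = rec$subject_id, pair = pair, side = side,
               t_onset = mus$t_onset[i], t_offset = mus$t_offset[i],
               r = antagonist_correlation(w), ci_uv = coactivation_index(w),
               n_samples = w$n_samples, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject = character(0), pair = character(0),
                      side = character(0), t_onset = double(0),
                      t_offset = double(0), r = double(0), ci_uv = double(0),
                      n_samples = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Aggregate coordination metrics across MUs, sides and subjects
#'
#' Averages r and CI across MUs within each (subject, pair, side) cell
#' (undefined correlations are excluded, not zeroed), then averages the two
#' sides per subject, then summarizes per pair (and per `group` column when
#' present). Empty cells are dropped with a warning.
#'
#' @param metrics data.frame as from [mu_coordination()], rows across MUs,
#'   sides, subjects; an optional `group` column stratifies the output.
#' @param average_sides average L/R per subject first (default TRUE).
#' @return data.frame with `pair` (and `group`), `n_subjects`, `mean_r`,
#'   `mean_ci_uv`.
#' @export
aggregate_coordination <- function(metrics, average_sides = TRUE) {
  if (nrow(metrics) == 0L) .stop_input("no coordination metrics to aggregate")
  has_group <- "group" %in% names(metrics)
  keys <- c("subject", if (has_group) "group", "pair",
            if (!average_sides) "side")
  cell_keys <- c(keys, if (average_sides) "side")
  cells <- unique(metrics[cell_keys])
  cells$mean_r <- NA_real_
  cells$mean_ci_uv <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(metrics))
    for (k in cell_keys) sel <- sel & metrics[[k]] == cells[[k]][i]
    r <- metrics$r[sel]
    if (all(is.na(r))) {
      warning("all correlations undefined in one cell; cell dropped from r")
    }
    cells$mean_r[i] <- mean(r, na.rm = TRUE)
    cells$mean_ci_uv[i] <- mean(metrics$ci_uv[sel])
  }
  if (average_sides) {
    subj <- unique(cells[keys])
    subj$mean_r <- NA_real_
    subj$mean_ci_uv <- NA_real_
    for (i in seq_len(nrow(subj))) {
      sel <- rep(TRUE, nrow(cells))
      for (k in keys) sel <- sel & cells[[k]] == subj[[k]][i]
      subj$mean_r[i] <- mean(cells$mean_r[sel], na.rm = TRUE)
      subj$mean_ci_uv[i] <- mean(cells$mean_ci_uv[sel])
    }
    cells <- subj
  }
  out_keys <- c(if (has_group) "group", "pair")
  groups <- unique(cells[out_keys])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(cells))
    for (k in out_keys) sel <- sel & cells[[k]] == groups[[k]][i]
    cbind(groups[i, , drop = FALSE],
          data.frame(n_subjects = length(unique(cells$subject[sel])),
                     mean_r = mean(cells$mean_r[sel], na.rm = TRUE),
                     mean_ci_uv = mean(cells$mean_ci_uv[sel])))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}
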