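#' Construct a stretch map
#'
#' A stretch map records, for each (joint, movement direction, muscle), whether
#' the muscle is being lengthened (`"stretching"`), shortened
#' (`"shortening"`) or `"unaffected"` by that passive movement. Every
#' (joint, direction) must name at least one stretching and one shortening
#' muscle, and no muscle may be both for the same movement.
#'
#' @param joint,direction,muscle,state parallel vectors of map entries.
#' @return data.frame of class `stretch_map`.
#' @export
stretch_map <- function(joint, direction, muscle, state) {
  df <- data.frame(joint = joint, direction = direction, muscle = muscle,
                   state = state, stringsAsFactors = FALSE)
  if (!all(df$joint %in% .JOINTS) || !all(df$direction %in% .DIRECTIONS) ||
      !all(df$muscle %in% .MUSCLES) ||
      !all(df$state %in% c("stretching", "shortening", "unaffected"))) {
    .stop_input("invalid stretch map entry")
  }
  key <- paste(df$joint, df$direction, df$muscle)
  if (anyDuplicated(key)) {
    .stop_input("muscle mapped twice for the same joint and direction")
  }
  for (jd in unique(paste(df$joint, df$direction))) {
    st <- df$state[paste(df$joint, df$direction) == jd]
    if (!"stretching" %in% st || !"shortening" %in% st) {
      .stop_input("each (joint, direction) needs a stretching and a shortening muscle")
    }
  }
  class(df) <- c("stretch_map", "data.frame")
  df
}

#' Default joint-muscle lengthening geometry
#'
#' Encodes which recorded muscle lengthens or shortens during each passive
#' movement, reflecting the biarticular anatomy of the thigh muscles: RF (hip
#' flexor, knee extensor) shortens during hip flexion and knee extension and
#' stretches during hip extension and knee flexion; BF mirrors it. At the
#' ankle, "flexion" means dorsiflexion (TA shortens, GL stretches) and
#' "extension" plantarflexion. At the elbow, BB shortens in flexion and TB in
#' extension. GL is deliberately left unaffected for knee movements: as a
#' biarticular muscle its length change during knee motion is ambiguous, so
#' only TA is interpreted there. All unlisted (joint, muscle) pairs are
#' unaffected.
#'
#' @return `stretch_map` data.frame.
#' @examples
#' m <- default_stretch_map()
#' stretch_state(m, "knee", "flexion", "RF")  # "stretching"
#' @export
default_stretch_map <- function() {
  stretch_map(
    joint = c("hip", "hip", "hip", "hip",
              "knee", "knee", "knee", "knee",
              "ankle", "ankle", "ankle", "ankle",
              "elbow", "elbow", "elbow", "elbow"),
    direction = rep(c("flexion", "flexion", "extension", "extension"), 4),
    muscle = c("RF", "BF", "RF", "BF",
               "RF", "BF", "RF", "BF",
               "TA", "GL", "TA", "GL",
               "BB", "TB", "BB", "TB"),
    state = c("shortening", "stretching", "stretching", "shortening",
              "stretching", "shortening", "shortening", "stretching",
              "shortening", "stretching", "stretching", "shortening",
              "shortening", "stretching", "stretching", "shortening"))
}

#' Look up the lengthening state of a muscle during a movement
#'
#' @param map `stretch_map`.
#' @param joint,direction,muscle vectors (recycled to a common length).
#' @return character vector of `"stretching"`, `"shortening"` or
#'   `"unaffected"` (the default for unmapped pairs).
#' @export
stretch_state <- function(map, joint, direction, muscle) {
  n <- max(length(joint), length(direction), length(muscle))
  joint <- rep_len(joint, n); direction <- rep_len(direction, n)
  muscle <- rep_len(muscle, n)
  key <- paste(joint, direction, muscle)
  mkey <- paste(map$joint, map$direction, map$muscle)
  st <- map$state[match(key, mkey)]
  st[is.na(st)] <- "unaffected"
  st
}

#' Classify EMG bursts as stretch or shortening responses
#'
#' A burst is assigned to the phase containing its onset (half-open
#' intervals), on the same side as its channel. It becomes a stretch response
#' (StR) if its muscle is being lengthened during that phase, a shortening
#' reaction (ShR) if shortened, and nothing if unaffected. Classification
#' requires the truncated duration — from onset to the earlier of burst
#' offset and phase end — to exceed `response_min_dur_s`, so activity
#' persisting past a direction change is only credited to the phase it began
#' in and its reported duration stops at the phase end. Bursts with onsets
#' outside every phase are ignored (counted in a message).
#'
#' @param bursts data.frame as from [detect_session_bursts()] (needs
#'   `muscle`, `side`, `t_onset`, `t_offset`; `mean_amp_uv` carried through).
#' @param phases [phase_annotation()].
#' @param map `stretch_map` (default [default_stretch_map()]).
#' @param response_min_dur_s minimum truncated duration in seconds.
#' @return data.frame with one row per response: `muscle`, `side`, `joint`,
#'   `direction`, `kind` ("StR"/"ShR"), `phase_index`, `t_onset`,
#'   `latency_ms`, `latency_pct`, `duration_s` (truncated), `duration_pct`,
#'   `mean_amp_uv`.
#' @export
classify_responses <- function(bursts, phases, map = default_stretch_map(),
                               response_min_dur_s = 0.100) {
  stopifnot(inherits(phases, "phase_annotation"))
  ph <- as.data.frame(phases)
  nb <- nrow(bursts)
  ## assign each burst onset to the (unique) phase containing it
  phase_row <- rep(NA_integer_, nb)
  for (key in unique(paste(ph$joint, ph$side))) {
    pidx <- which(paste(ph$joint, ph$side) == key)
    pd <- ph[pidx, ]  # sorted by t_start within a trial
    bi <- which(bursts$side == pd$side[1L] & is.na(phase_row))
    if (!length(bi)) next
    j <- findInterval(bursts$t_onset[bi], pd$t_start)
    ok <- j >= 1L & bursts$t_onset[bi] < pd$t_end[pmax(j, 1L)]
    phase_row[bi[ok]] <- pidx[j[ok]]
  }
  n_unassigned <- sum(is.na(phase_row))
  if (n_unassigned > 0L) {
    message(n_unassigned, " burst(s) outside all annotated phases ignored")
  }
  keep <- !is.na(phase_row)
  b <- bursts[keep, , drop = FALSE]
  p <- ph[phase_row[keep], , drop = FALSE]
  st <- stretch_state(map, p$joint, p$direction, b$muscle)
  dur <- pmin(b$t_offset, p$t_end) - b$t_onset
  ## strict "longer than" with a relative guard so that durations equal to
  ## the threshold up to floating-point noise are excluded
  keep2 <- st != "unaffected" & dur > response_min_dur_s * (1 + 1e-9)
  b <- b[keep2, , drop = FALSE]
  p <- p[keep2, , drop = FALSE]
  st <- st[keep2]
  dur <- dur[keep2]
  phase_dur <- p$t_end - p$t_start
  res <- data.frame(
    muscle = b$muscle, side = b$side, joint = p$joint,
    direction = p$direction,
    kind = as.character(ifelse(st == "stretching", "StR", "ShR")),
    phase_index = p$phase_index, t_onset = b$t_onset,
    latency_ms = (b$t_onset - p$t_start) * 1000,
    latency_pct = 100 * (b$t_onset - p$t_start) / phase_dur,
    duration_s = dur, duration_pct = 100 * dur / phase_dur,
    mean_amp_uv = if ("mean_amp_uv" %in% names(b)) b$mean_amp_uv else
      rep(NA_real_, nrow(b)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Occurrence of StR/ShR per muscle, joint and direction
#'
#' The occurrence of a response type is the proportion of flexion (or
#' extension) movements in which at least one such response was present —
#' multiple bursts within one phase count once. Rows are produced for every
#' response type the stretch map allows (a lengthened muscle can show StR, a
#' shortened one ShR), including 0% rows when movements exist but no response
#' occurred. With `pool_sides` the left and right limbs are pooled by summing
#' counts.
#'
#' @param responses data.frame from [classify_responses()].
#' @param phases [phase_annotation()].
#' @param map `stretch_map` used for classification.
#' @param pool_sides pool left/right counts (default TRUE).
#' @return data.frame with `muscle`, `joint`, `direction`, `kind`
#'   (plus `side` when not pooling), `n_movements`, `n_with_response`,
#'   `occurrence_pct`.
#' @export
occurrence <- function(responses, phases, map = default_stretch_map(),
                       pool_sides = TRUE) {
  stopifnot(inherits(phases, "phase_annotation"))
  ph <- as.data.frame(phases)
  cells <- unique(ph[c("joint", "direction", if (!pool_sides) "side")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    musc <- map[map$joint == cell$joint & map$direction == cell$direction &
                  map$state != "unaffected", ]
    sel_ph <- ph$joint == cell$joint & ph$direction == cell$direction
    if (!pool_sides) sel_ph <- sel_ph & ph$side == cell$side
    n_mov <- sum(sel_ph)
    if (n_mov == 0L) {
      warning("no movements for ", cell$joint, " ", cell$direction)
      next
    }
    for (m in seq_len(nrow(musc))) {
      kind <- if (musc$state[m] == "stretching") "StR" else "ShR"
      sel <- responses$joint == cell$joint &
        responses$direction == cell$direction &
        responses$muscle == musc$muscle[m] & responses$kind == kind
      if (!pool_sides) sel <- sel & responses$side == cell$side
      hit <- responses[sel, c("side", "phase_index")]
      n_with <- nrow(unique(hit))
      row <- data.frame(muscle = musc$muscle[m], joint = cell$joint,
                        direction = cell$direction, kind = kind,
                        n_movements = n_mov, n_with_response = n_with,
                        occurrence_pct = 100 * n_with / n_mov,
                        stringsAsFactors = FALSE)
      if (!pool_sides) row$side <- cell$side
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Histogram of normalized response latencies
#'
#' Bins response latencies expressed as a percentage of the flexion/extension
#' phase duration, with half-open bins `[lo, hi)`.
#'
#' @param responses data.frame from [classify_responses()] (needs
#'   `latency_pct`).
#' @param bins_pct bin breaks in percent (default width-10 bins over 0–100).
#' @return data.frame `bin_lo`, `bin_hi`, `count`; counts sum to the number
#'   of responses.
#' @export
latency_histogram <- function(responses, bins_pct = seq(0, 100, by = 10)) {
  if (nrow(responses) == 0L) .stop_input("no responses to histogram")
  x <- responses$latency_pct
  if (any(x < bins_pct[1L] | x >= bins_pct[length(bins_pct)])) {
    .stop_input("latencies outside the bin range")
  }
  idx <- findInterval(x, bins_pct)
  k <- length(bins_pct) - 1L
  data.frame(bin_lo = bins_pct[-length(bins_pct)], bin_hi = bins_pct[-1L],
             count = tabulate(idx, nbins = k))
}

#' Screen distant muscles for phase-locked (rhythmic) activity
#'
#' During passive movements of one joint, muscles of joints not being moved
#' sometimes respond consistently across consecutive movement cycles. This
#' screen flags a distant muscle as rhythmic when, in at least `lock_frac` of
#' the phases of one direction (whichever direction locks more often), the
#' muscle has at least one burst onset inside that phase. Trials with fewer
#' than `min_cycles` complete flexion/extension cycles are not evaluable
#' (returned `NA`, distinct from FALSE).
#'
#' @param bursts burst table for the distant muscle's channel (needs `side`,
#'   `t_onset`).
#' @param phases [phase_annotation()] of the moved joint (one trial).
#' @param min_cycles minimum number of complete cycles (default 3).
#' @param lock_frac required fraction of locked phases (default 0.5).
#' @return list with `rhythmic` (TRUE/FALSE/NA), `n_cycles`, `n_locked`,
#'   `direction` (the locking direction).
#' @export
detect_rhythmic_distant <- function(bursts, phases, min_cycles = 3L,
                                    lock_frac = 0.5) {
  stopifnot(inherits(phases, "phase_annotation"))
  ph <- as.data.frame(phases)
  n_cycles <- min(sum(ph$direction == "flexion"),
                  sum(ph$direction == "extension"))
  if (n_cycles < min_cycles) {
    return(list(rhythmic = NA, n_cycles = n_cycles, n_locked = NA_integer_,
                direction = NA_character_))
  }
  hits <- vapply(.DIRECTIONS, function(d) {
    pd <- ph[ph$direction == d, , drop = FALSE]
    sum(vapply(seq_len(nrow(pd)), function(i) {
      any(bursts$side == pd$side[i] & bursts$t_onset >= pd$t_start[i] &
            bursts$t_onset < pd$t_end[i])
    }, logical(1)))
  }, integer(1))
  n_phase <- vapply(.DIRECTIONS,
                    function(d) sum(ph$direction == d), integer(1))
  frac <- hits / n_phase
  best <- which.max(frac)
  list(rhythmic = unname(frac[best] >= lock_frac),
       n_cycles = n_cycles, n_locked = unname(hits[best]),
       direction = .DIRECTIONS[best])
}
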