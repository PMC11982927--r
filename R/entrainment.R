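#' Sequential turn pairs within a turn sequence
#'
#' Pairs `(t_i, t_{i+1})` of consecutive turns. Entrainment proximity is a
#' between-interlocutor quantity, so by default consecutive turns by the same
#' speaker are skipped (a same-speaker pair measures self-consistency);
#' `pairs = "all"` keeps them for sensitivity analyses.
#'
#' @param turns Time-ordered turn table.
#' @param pairs `"cross-speaker"` (default) or `"all"`.
#' @return Data frame of row indices `i`, `j` into `turns` (may be empty).
#' @export
sequential_pairs <- function(turns, pairs = c("cross-speaker", "all")) {
  pairs <- match.arg(pairs)
  n <- nrow(turns)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0)))
  i <- seq_len(n - 1L)
  j <- i + 1L
  if (pairs == "cross-speaker") {
    keep <- turns$speaker[i] != turns$speaker[j]
    i <- i[keep]; j <- j[keep]
  }
  data.frame(i = i, j = j)
}

#' Acoustic-prosodic proximity for one event
#'
#' For each of the six turn-level features, the absolute difference is taken
#' across each sequential pair of turns in the event and averaged over all
#' such pairs, giving one proximity value per feature per event (smaller =
#' interlocutors closer in prosodic space). Pairs with a missing feature on
#' either side are dropped per feature. Events whose assigned turns involve
#' fewer than two distinct speakers are flagged `single_speaker`, carry no
#' proximity values, and are excluded from entrainment modelling.
#'
#' @param turns Turn table with prosody columns from [turn_prosody()].
#' @param start,end Event window (seconds).
#' @param pairs Passed to [sequential_pairs()].
#' @return One-row data frame: `d_mean_pitch`, `d_max_pitch`, `d_min_pitch`,
#'   `d_mean_int`, `d_max_int`, `d_min_int`, matching `n_*` pair counts,
#'   `n_turns`, `n_speakers`, and a `status` of `"ok"`, `"single_speaker"`
#'   or `"no_pairs"`.
#' @export
event_proximity <- function(turns, start, end, pairs = c("cross-speaker", "all")) {
  tw <- turns_in_event(turns, start, end)
  d <- setNames(rep(NA_real_, 6L), paste0("d_", .prox_cols))
  np <- setNames(rep(0L, 6L), paste0("n_", .prox_cols))
  n_speakers <- length(unique(tw$speaker))
  status <- "ok"
  if (n_speakers < 2L) {
    status <- "single_speaker"
  } else {
    pr <- sequential_pairs(tw, pairs)
    if (nrow(pr) == 0L) {
      status <- "no_pairs"
    } else {
      for (k in seq_along(.feat_cols)) {
        a <- tw[[.feat_cols[k]]][pr$i]
        b <- tw[[.feat_cols[k]]][pr$j]
        ok <- !is.na(a) & !is.na(b)
        np[k] <- sum(ok)
        if (np[k] > 0L) d[k] <- mean(abs(b[ok] - a[ok]))
      }
      if (all(np == 0L)) status <- "no_pairs"
    }
  }
  cbind(data.frame(as.list(d)), data.frame(as.list(np)),
        data.frame(n_turns = nrow(tw), n_speakers = n_speakers,
                   status = status))
}

.prox_cols <- c("mean_pitch", "max_pitch", "min_pitch",
                "mean_int", "max_int", "min_int")

#' Proximity table for all events of a session
#'
#' @param events Event table ([read_event_sheet()]).
#' @param turns Turn table with prosody columns.
#' @param pairs Passed to [sequential_pairs()].
#' @return Data frame with one row per event (`event` index column first).
#' @export
event_proximity_table <- function(events, turns, pairs = c("cross-speaker", "all")) {
  pairs <- match.arg(pairs)
  rows <- lapply(seq_len(nrow(events)), function(i)
    event_proximity(turns, events$start[i], events$end[i], pairs))
  cbind(data.frame(event = seq_len(nrow(events))), do.call(rbind, rows))
}

#' Restrict a proximity table to events usable for entrainment modelling
#'
#' Keeps events with at least one valid proximity value; reports how many
#' were excluded as single-speaker and how many for missing features.
#'
#' @param prox Proximity table from [event_proximity_table()].
#' @return List: `kept` (sub-table), `counts` (named: kept,
#'   excluded_single_speaker, excluded_missing).
#' @export
filter_entrainment_events <- function(prox) {
  single <- prox$status == "single_speaker"
  missing <- !single & prox$status == "no_pairs"
  kept <- prox[!single & !missing, , drop = FALSE]
  list(kept = kept,
       counts = c(kept = nrow(kept),
                  excluded_single_speaker = sum(single),
                  excluded_missing = sum(missing)))
}
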