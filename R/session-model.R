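#' Speaker group from diarization marker
#'
#' Maps markers to analysis groups: `H` is the host, `C` the younger control
#' subject, `F1..F9`/`M1..M7` are older-adult participants, and `N`
#' (noise) / `SO` (significant over-speak) are excluded from all analyses.
#'
#' @param code Character vector of diarization markers.
#' @return Character vector in `{host, control, participant, excluded}`.
#' @export
speaker_group <- function(code) {
  bad <- setdiff(unique(code), .speaker_labels)
  if (length(bad))
    stop("unknown speaker marker(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- rep("participant", length(code))
  out[code == "H"] <- "host"
  out[code == "C"] <- "control"
  out[code %in% c("N", "SO")] <- "excluded"
  out
}

#' Build speaker turns from diarization intervals
#'
#' Drops excluded (`N`, `SO`) spans, then merges consecutive intervals of the
#' same speaker whose separating gap is at most `merge_gap` seconds into a
#' single turn ("consecutive" is judged in the time-ordered sequence that
#' remains after the drop, so an intervening other-speaker interval always
#' breaks a merge). A bridged gap widens the turn's span but is never counted
#' as speech: each turn carries a `speech` column equal to the summed
#' duration of its source intervals, and the source intervals themselves are
#' kept in the `"segments"` attribute for occupancy computations.
#'
#' @param intervals Data frame `start`, `end`, `label` as returned by
#'   [read_diarization()].
#' @param merge_gap Maximum silent gap (seconds) bridged within one speaker's
#'   turn. Default 0: only exactly adjacent intervals merge.
#' @return Data frame of turns: `speaker`, `group`, `start`, `end`, `speech`,
#'   time-ordered, with attribute `segments` (columns `turn`, `speaker`,
#'   `start`, `end`).
#' @export
build_turns <- function(intervals, merge_gap = 0) {
  x <- .validate_intervals(intervals)
  x$group <- speaker_group(x$label)
  x <- x[x$group != "excluded", , drop = FALSE]
  x <- x[order(x$start, x$end), , drop = FALSE]
  # same-speaker intervals must not overlap
  for (sp in unique(x$label)) {
    xs <- x[x$label == sp, , drop = FALSE]
    if (nrow(xs) > 1L && any(xs$start[-1] < xs$end[-nrow(xs)]))
      stop("overlapping intervals for speaker ", sp, call. = FALSE)
  }
  n <- nrow(x)
  if (n == 0L) {
    out <- data.frame(speaker = character(0), group = character(0),
                      start = numeric(0), end = numeric(0), speech = numeric(0))
    attr(out, "segments") <- data.frame(turn = integer(0), speaker = character(0),
                                        start = numeric(0), end = numeric(0))
    return(out)
  }
  new_turn <- c(TRUE, x$label[-1] != x$label[-n] |
                      x$start[-1] - x$end[-n] > merge_gap)
  id <- cumsum(new_turn)
  out <- data.frame(
    speaker = x$label[new_turn],
    group   = x$group[new_turn],
    start   = unname(tapply(x$start, id, min)[as.character(seq_len(max(id)))]),
    end     = unname(tapply(x$end, id, max)[as.character(seq_len(max(id)))]),
    speech  = unname(tapply(x$end - x$start, id, sum)[as.character(seq_len(max(id)))]),
    row.names = NULL
  )
  attr(out, "segments") <- data.frame(turn = id, speaker = x$label,
                                      start = x$start, end = x$end,
                                      row.names = NULL)
  out
}

#' Turns assigned to an event window
#'
#' A turn belongs to an event when its temporal overlap with the event window
#' strictly exceeds half the turn's span; an exact 50% overlap is excluded.
#' This resolves turns that straddle an event boundary (a single event
#' usually spans several speaker turns).
#'
#' @param turns Turn table from [build_turns()].
#' @param start,end Event window in seconds.
#' @return The subset of `turns` assigned to the window, time-ordered.
#' @export
turns_in_event <- function(turns, start, end) {
  if (end <= start) stop("event window must have start < end", call. = FALSE)
  ov <- pmin(turns$end, end) - pmax(turns$start, start)
  keep <- ov > (turns$end - turns$start) / 2
  out <- turns[keep, , drop = FALSE]
  seg <- attr(turns, "segments")
  if (!is.null(seg))
    attr(out, "segments") <- seg[seg$turn %in% which(keep), , drop = FALSE]
  out
}

#' Number of distinct speakers in an event window
#'
#' A diagnostic cross-check for the coded "number speaking" column (which
#' remains authoritative for modelling: it is what the raters recorded).
#'
#' @inheritParams turns_in_event
#' @return Integer count of distinct speaker markers among the event's turns.
#' @export
distinct_speakers <- function(turns, start, end) {
  length(unique(turns_in_event(turns, start, end)$speaker))
}
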