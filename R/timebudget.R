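# Union length of possibly-overlapping intervals clipped to [ws, we].
.coverage <- function(start, end, ws, we) {
  s <- pmax(start, ws); e <- pmin(end, we)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (all(s[-1] >= e[-length(e)])) return(sum(e - s))
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (k in seq_along(s)[-1]) {
    if (s[k] > cur_e) { tot <- tot + (cur_e - cur_s); cur_s <- s[k]; cur_e <- e[k] }
    else cur_e <- max(cur_e, e[k])
  }
  tot + (cur_e - cur_s)
}

# speech segments (post N/SO removal) for occupancy; falls back to turn spans
# when build_turns' segments attribute is absent (identical when merge_gap=0).
.speech_segments <- function(turns) {
  seg <- attr(turns, "segments")
  if (is.null(seg))
    seg <- data.frame(turn = seq_len(nrow(turns)), speaker = turns$speaker,
                      start = turns$start, end = turns$end)
  seg$group <- speaker_group(seg$speaker)
  seg
}

#' Speech time-budget features for a time window
#'
#' For an event window (or any window), the amount of time each speaker
#' group spoke (turn time clipped to the window; bridged merge gaps never
#' count as speech), the fraction of speech time contributed by the older
#' adult participants, and the fraction of the window that is silent (not
#' covered by any host/control/participant speech; noise and over-speak
#' spans were excluded upstream and therefore count as silence).
#'
#' @param turns Turn table from [build_turns()].
#' @param start,end Window in seconds, `start < end`.
#' @param fraction_denominator `"speech"` (default): participant fraction is
#'   participant time over total speech time; `"window"`: over the window
#'   duration.
#' @return One-row data frame: `host_time`, `control_time`,
#'   `participant_time` (seconds), `participant_fraction` (NA when the
#'   window holds no speech), `silence_fraction`, `start`, `end`.
#' @export
window_time_features <- function(turns, start, end,
                                 fraction_denominator = c("speech", "window")) {
  .window_tf(.speech_segments(turns), start, end,
             match.arg(fraction_denominator))
}

.window_tf <- function(seg, start, end, fraction_denominator = "speech") {
  if (end <= start) stop("window must have start < end", call. = FALSE)
  clip <- pmin(seg$end, end) - pmax(seg$start, start)
  clip[clip < 0] <- 0
  gt <- function(g) sum(clip[seg$group == g])
  host_time <- gt("host"); control_time <- gt("control")
  participant_time <- gt("participant")
  speech <- host_time + control_time + participant_time
  denom <- if (fraction_denominator == "speech") speech else (end - start)
  participant_fraction <- if (denom > 0) participant_time / denom else NA_real_
  covered <- .coverage(seg$start, seg$end, start, end)
  data.frame(host_time = host_time, control_time = control_time,
             participant_time = participant_time,
             participant_fraction = participant_fraction,
             silence_fraction = 1 - covered / (end - start),
             start = start, end = end)
}

#' Time-budget features for every event
#'
#' @param events Event table ([read_event_sheet()]).
#' @param turns Turn table from [build_turns()].
#' @param ... Passed to [window_time_features()].
#' @return Data frame, one row per event, `event` index column first.
#' @export
event_time_features <- function(events, turns, ...) {
  seg <- .speech_segments(turns)
  rows <- lapply(seq_len(nrow(events)), function(i)
    .window_tf(seg, events$start[i], events$end[i], ...))
  cbind(data.frame(event = seq_len(nrow(events))), do.call(rbind, rows))
}

#' Per-group speech shares over a whole session
#'
#' Percentages of total speech time by speaker group, plus the silent
#' percentage of the session span. Sessions built around egalitarian games
#' typically show participant shares above 40%.
#'
#' @param turns Turn table from [build_turns()].
#' @param span Session span `c(start, end)`; defaults to `[0, max turn end]`.
#' @return One-row data frame: `host_pct`, `control_pct`, `participant_pct`
#'   (shares of speech time, summing to 100 when there is speech) and
#'   `silence_pct` (share of the span).
#' @export
session_speech_share <- function(turns, span = NULL) {
  if (is.null(span)) span <- c(0, if (nrow(turns)) max(turns$end) else 0)
  if (span[2] <= span[1]) stop("empty session span", call. = FALSE)
  tf <- window_time_features(turns, span[1], span[2])
  speech <- tf$host_time + tf$control_time + tf$participant_time
  pct <- function(x) if (speech > 0) 100 * x / speech else NA_real_
  data.frame(host_pct = pct(tf$host_time), control_pct = pct(tf$control_time),
             participant_pct = pct(tf$participant_time),
             silence_pct = 100 * tf$silence_fraction)
}

#' Percentile of a turn length within a reference set
#'
#' `100 * (# reference durations <= this duration) / N`: the longest turn in
#' the reference set sits at the 100th percentile. Used to locate unusually
#' long participant turns (spontaneous prolonged discussions).
#'
#' @param duration Numeric vector of turn durations (seconds).
#' @param reference Non-empty numeric vector of reference durations.
#' @return Percentiles in `[0, 100]`, same length as `duration`.
#' @export
turn_length_percentile <- function(duration, reference) {
  if (!length(reference)) stop("empty reference set", call. = FALSE)
  vapply(duration, function(d) 100 * mean(reference <= d), numeric(1))
}

#' Share of speech time held by one speaker in a session
#'
#' @param turns Turn table from [build_turns()].
#' @param speaker Speaker marker (e.g. `"M3"`).
#' @return Percent of total speech time (0 when the speaker is absent).
#'   The denominator is total speech time, not the session span.
#' @export
speaker_case_share <- function(turns, speaker) {
  total <- sum(turns$speech)
  if (total == 0) return(0)
  100 * sum(turns$speech[turns$speaker == speaker]) / total
}
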