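# Valid diarization labels: H host, C control, F1..F9 / M1..M7 participants,
# N noise, SO significant over-speak.
.speaker_labels <- c("H", "C", paste0("F", 1:9), paste0("M", 1:7), "N", "SO")

#' Construct a time-value tier (pitch or intensity track)
#'
#' A tier is the in-memory form of a Praat PitchTier or IntensityTier: an
#' ordered set of `(time, value)` points sampled over a session, in seconds
#' and Hz (pitch) or dB (intensity).
#'
#' @param time Numeric vector of times in seconds, strictly increasing, >= 0.
#' @param value Numeric vector of values; Hz for pitch (must be positive),
#'   dB for intensity (any finite value).
#' @param kind `"pitch"` or `"intensity"`.
#' @param session_id Optional session identifier.
#' @return A data frame with columns `time` and `value`, class
#'   `"engage_tier"`, with attributes `kind` and `session_id`.
#' @export
tier <- function(time, value, kind = c("pitch", "intensity"), session_id = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(length(time) == length(value))
  x <- data.frame(time = as.numeric(time), value = as.numeric(value))
  attr(x, "kind") <- kind
  attr(x, "session_id") <- session_id
  class(x) <- c("engage_tier", "data.frame")
  validate_tier(x)
}

#' Validate a tier against its invariants
#'
#' Checks strictly increasing non-negative times, finite values, and
#' positivity for pitch.
#'
#' @param x An `engage_tier`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_tier <- function(x) {
  kind <- attr(x, "kind")
  if (nrow(x)) {
    if (any(!is.finite(x$time)) || any(!is.finite(x$value)))
      stop("tier contains non-finite times or values", call. = FALSE)
    if (any(x$time < 0))
      stop("tier times must be >= 0", call. = FALSE)
    if (any(diff(x$time) <= 0))
      stop("tier times must be strictly increasing", call. = FALSE)
    if (identical(kind, "pitch") && any(x$value <= 0))
      stop("pitch values must be > 0 Hz", call. = FALSE)
  }
  x
}

# Praat text-file tiers come in two dialects. The long form labels every
# field ("points [1]: / number = 0.0 / value = 100"); the short form lists
# bare numbers after the two header lines. Both start with:
#   File type = "ooTextFile"
#   Object class = "PitchTier"  (or "IntensityTier")
.read_praat_tier <- function(path, expect_class) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) < 2L || !grepl("^File type\\s*=\\s*\"ooTextFile\"", lines[1]))
    stop("not a Praat text file (line 1): ", path, call. = FALSE)
  m <- regmatches(lines[2], regexec("^Object class\\s*=\\s*\"([^\"]+)\"", lines[2]))[[1]]
  if (length(m) < 2L)
    stop("malformed Praat header (line 2): ", lines[2], call. = FALSE)
  if (m[2] != expect_class)
    stop("expected Object class \"", expect_class, "\" but found \"", m[2],
         "\" in ", path, call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  long <- any(grepl("=", body))
  if (long) {
    num <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), body, value = TRUE)
      as.numeric(sub(".*=\\s*", "", hit))
    }
    n <- {
      hit <- grep("^points:\\s*size\\s*=", body, value = TRUE)
      if (!length(hit)) stop("malformed long-form tier: missing 'points: size ='",
                             call. = FALSE)
      as.integer(sub(".*=\\s*", "", hit[1]))
    }
    times <- num("number")
    values <- num("value")
    if (length(times) != n || length(values) != n)
      stop("long-form tier declares ", n, " points but lists ",
           length(times), " times / ", length(values), " values", call. = FALSE)
  } else {
    vals <- suppressWarnings(as.numeric(body))
    if (any(is.na(vals)))
      stop("malformed short-form tier: non-numeric line '",
           body[which(is.na(vals))[1]], "'", call. = FALSE)
    if (length(vals) < 3L)
      stop("malformed short-form tier: header truncated", call. = FALSE)
    n <- as.integer(vals[3])
    pts <- vals[-(1:3)]
    if (length(pts) != 2L * n)
      stop("short-form tier declares ", n, " points but lists ",
           length(pts) / 2, call. = FALSE)
    idx <- seq_len(n) * 2L - 1L
    times <- pts[idx]
    values <- pts[idx + 1L]
  }
  list(time = times, value = values)
}

#' Read a Praat PitchTier
#'
#' Accepts both Praat text dialects (long, with `field = value` lines, and
#' short, with bare numbers); the dialect is detected from the body.
#'
#' @param path Path to a PitchTier text file.
#' @param session_id Optional session identifier stored on the result.
#' @return An [tier()] of kind `"pitch"`.
#' @export
read_pitch_tier <- function(path, session_id = NA_character_) {
  p <- .read_praat_tier(path, "PitchTier")
  tier(p$time, p$value, kind = "pitch", session_id = session_id)
}

#' Read a Praat IntensityTier
#'
#' @inheritParams read_pitch_tier
#' @return An [tier()] of kind `"intensity"`. Intensity values may be zero or
#'   negative (dB is a relative scale).
#' @export
read_intensity_tier <- function(path, session_id = NA_character_) {
  p <- .read_praat_tier(path, "IntensityTier")
  tier(p$time, p$value, kind = "intensity", session_id = session_id)
}

#' Write a tier as a Praat text file
#'
#' @param x An [tier()].
#' @param path Output path.
#' @param format `"short"` (default) or `"long"` Praat text dialect.
#' @return `path`, invisibly.
#' @export
write_tier <- function(x, path, format = c("short", "long")) {
  format <- match.arg(format)
  validate_tier(x)
  cls <- if (identical(attr(x, "kind"), "pitch")) "PitchTier" else "IntensityTier"
  xmin <- if (nrow(x)) min(x$time) else 0
  xmax <- if (nrow(x)) max(x$time) else 0
  num <- function(v) formatC(v, format = "g", digits = 17)
  if (format == "short") {
    out <- c(
      "File type = \"ooTextFile\"",
      paste0("Object class = \"", cls, "\""),
      "",
      num(xmin), num(xmax), as.character(nrow(x)),
      as.vector(rbind(num(x$time), num(x$value)))[seq_len(2L * nrow(x))]
    )
  } else {
    pts <- character(0)
    if (nrow(x)) {
      pts <- as.vector(rbind(
        paste0("points [", seq_len(nrow(x)), "]:"),
        paste0("    number = ", num(x$time)),
        paste0("    value = ", num(x$value))
      ))
    }
    out <- c(
      "File type = \"ooTextFile\"",
      paste0("Object class = \"", cls, "\""),
      "",
      paste0("xmin = ", num(xmin)),
      paste0("xmax = ", num(xmax)),
      paste0("points: size = ", nrow(x)),
      pts
    )
  }
  writeLines(out, path)
  invisible(path)
}

.validate_intervals <- function(x) {
  bad <- setdiff(unique(x$label), c(.speaker_labels, ""))
  if (length(bad))
    stop("unknown diarization label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(x$end <= x$start))
    stop("diarization interval with end <= start at row(s) ",
         paste(which(x$end <= x$start), collapse = ", "), call. = FALSE)
  x[x$label != "", , drop = FALSE]
}

#' Read a speaker diarization log
#'
#' Reads "who spoke when" as labeled time intervals. Two on-disk forms are
#' accepted and normalized to the same interval table: a Praat TextGrid
#' containing an interval tier (long text dialect), or a headerless 3-column
#' tab-separated log `start<TAB>end<TAB>label`. Labels are restricted to the
#' study marker set: `H` (host), `C` (control), `F1`..`F9` and `M1`..`M7`
#' (female/male participants), `N` (noise), `SO` (significant over-speak).
#' Empty labels (unlabelled stretches of a TextGrid) are dropped.
#'
#' @param path Path to a TextGrid or TSV diarization file.
#' @return A data frame with columns `start`, `end` (seconds) and `label`,
#'   in file order.
#' @export
read_diarization <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^File type", first)) {
    lines <- trimws(readLines(path, warn = FALSE))
    if (!any(grepl("class\\s*=\\s*\"IntervalTier\"", lines)))
      stop("TextGrid contains no IntervalTier: ", path, call. = FALSE)
    # take fields from the first interval tier onwards
    start_at <- grep("class\\s*=\\s*\"IntervalTier\"", lines)[1]
    lines <- lines[start_at:length(lines)]
    xmin <- as.numeric(sub(".*=\\s*", "", grep("^xmin\\s*=", lines, value = TRUE)))
    xmax <- as.numeric(sub(".*=\\s*", "", grep("^xmax\\s*=", lines, value = TRUE)))
    text <- sub("^text\\s*=\\s*\"(.*)\"\\s*$", "\\1",
                grep("^text\\s*=", lines, value = TRUE))
    # first xmin/xmax pair describes the tier itself, not an interval
    if (length(xmin) != length(text) + 1L)
      stop("malformed TextGrid interval tier in ", path, call. = FALSE)
    out <- data.frame(start = xmin[-1], end = xmax[-1], label = text,
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("start", "end", "label"),
                             colClasses = c("numeric", "numeric", "character"),
                             quote = "", comment.char = "")
  }
  .validate_intervals(out)
}

#' Write a diarization log as 3-column TSV
#'
#' @param x Data frame with `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diarization <- function(x, path) {
  utils::write.table(x[, c("start", "end", "label")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical event-sheet columns; score_r2 optional.
.event_cols <- c("topic", "start", "end",
                 "social", "humor", "game", "cue", "affirm", "disclose",
                 "correct", "nonverbal", "number",
                 "host1", "host2", "host3", "score_r1")
.event_code_cols <- c("social", "humor", "game", "cue", "affirm",
                      "disclose", "correct", "nonverbal")

# Header aliases seen in coded spreadsheets; deposited sheets may differ in
# naming, so map by alias and fall back to position when the width matches.
.event_aliases <- list(
  topic = c("topic"), start = c("start", "start_s", "start_time"),
  end = c("end", "end_s", "end_time"),
  social = "social", humor = "humor", game = c("game", "game_qa"),
  cue = c("cue", "cuing", "host_cuing"), affirm = c("affirm", "affirmation"),
  disclose = c("disclose", "disc", "disclosure", "self_disclosure"),
  correct = c("correct", "correction", "host_correction"),
  nonverbal = c("nonverbal", "nverb", "non_verbal", "nverbal"),
  number = c("number", "n_speaking", "num"),
  host1 = c("host1", "host_1"), host2 = c("host2", "host_2"),
  host3 = c("host3", "host_3"),
  score_r1 = c("score_r1", "score", "score1"),
  score_r2 = c("score_r2", "score2")
)

.validate_events <- function(x) {
  if (any(x$start >= x$end))
    stop("event with start >= end at row(s) ",
         paste(which(x$start >= x$end), collapse = ", "), call. = FALSE)
  flags <- c(.event_code_cols, "host1", "host2", "host3")
  for (cl in flags)
    if (!all(x[[cl]] %in% c(0, 1)))
      stop("column '", cl, "' must be binary 0/1", call. = FALSE)
  if (any(rowSums(x[, c("host1", "host2", "host3")]) > 1))
    stop("host indicator columns must be one-hot (at most one 1)", call. = FALSE)
  if (any(x$number < 1 | x$number != round(x$number)))
    stop("'number' (number speaking) must be a positive integer", call. = FALSE)
  score_cols <- intersect(c("score_r1", "score_r2"), names(x))
  for (cl in score_cols) {
    s <- x[[cl]]
    s <- s[!is.na(s)]
    if (any(s < 1 | s > 5 | s != round(s)))
      stop("engagement scores in '", cl, "' must be integers in 1..5",
           call. = FALSE)
  }
  x
}

#' Read a coded event sheet
#'
#' One row per coded event: topic, start/end times (seconds), eight binary
#' behavior codes (social, humor, game, cue, affirm, disclose, correct,
#' nonverbal), the number of people speaking, three host indicator columns
#' (all zero encodes Host 4), and one or two raters' Likert engagement
#' scores (1 = lowest, 5 = highest).
#'
#' Columns are matched by name through a small alias table; a headerless or
#' unrecognized header sheet with the canonical column count is mapped by
#' position.
#'
#' @param path Path to a CSV event sheet.
#' @return A validated data frame with canonical column names, class
#'   `"engage_events"`.
#' @export
read_event_sheet <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(raw))))
  want <- c(.event_cols, "score_r2")
  out <- list()
  for (cl in want) {
    hit <- which(nm %in% .event_aliases[[cl]])
    if (length(hit)) out[[cl]] <- raw[[hit[1]]]
  }
  if (!all(.event_cols %in% names(out))) {
    if (ncol(raw) %in% c(16L, 17L)) {
      # positional fallback, Table-1 column order
      names(raw) <- want[seq_len(ncol(raw))]
      out <- raw
    } else {
      stop("event sheet is missing required column(s): ",
           paste(setdiff(.event_cols, names(out)), collapse = ", "),
           call. = FALSE)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  for (cl in setdiff(names(out), "topic")) {
    # tolerate "179 s" style cells
    if (is.character(out[[cl]]))
      out[[cl]] <- as.numeric(gsub("[^0-9.eE+-]", "", out[[cl]]))
  }
  out <- .validate_events(out)
  class(out) <- c("engage_events", "data.frame")
  out
}

#' Write a coded event sheet as CSV
#'
#' @param x Event data frame as returned by [read_event_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_sheet <- function(x, path) {
  keep <- intersect(c(.event_cols, "score_r2"), names(x))
  utils::write.csv(as.data.frame(x)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Host identity from the one-hot indicator columns
#'
#' Hosts 1-3 are flagged by their own indicator; all-zero rows encode Host 4.
#'
#' @param events Event data frame with `host1`, `host2`, `host3`.
#' @return Integer vector of host ids in 1..4.
#' @export
host_id <- function(events) {
  ifelse(events$host1 == 1, 1L,
         ifelse(events$host2 == 1, 2L,
                ifelse(events$host3 == 1, 3L, 4L)))
}
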