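# Fixed turn-at-talk color scheme: host red, female participants blue,
# male participants green, younger control black.
.tat_color <- function(speaker) {
  first <- substr(speaker, 1, 1)
  unname(c(H = "red", F = "blue", M = "green", C = "black")[first])
}

#' Serialized segment list for a turn-at-talk graph
#'
#' The structural form of the figure: one row per turn with its speaker
#' lane, span and color, so tests and downstream tools can assert on the
#' graph without image comparison.
#'
#' @param turns Turn table from [build_turns()].
#' @return Data frame `speaker`, `lane` (1 = host lane at top, then control,
#'   then participants by marker), `start`, `end`, `color`.
#' @export
turn_at_talk_segments <- function(turns) {
  if (!nrow(turns)) stop("empty session: no turns to draw", call. = FALSE)
  speakers <- unique(turns$speaker)
  grp <- speaker_group(speakers)
  ord <- order(match(grp, c("host", "control", "participant")), speakers)
  lanes <- setNames(seq_along(speakers), speakers[ord])
  data.frame(speaker = turns$speaker,
             lane = unname(lanes[turns$speaker]),
             start = turns$start, end = turns$end,
             color = .tat_color(turns$speaker))
}

#' Write a segment list as JSON
#'
#' @param segments Output of [turn_at_talk_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_json <- function(segments, path) {
  jsonlite::write_json(segments, path, digits = NA)
  invisible(path)
}

#' Turn-at-talk graph
#'
#' Timeline of color-coded speaker turns, one lane per speaker (host red,
#' female participants blue, male participants green, control black), with
#' an optional normalized pitch trace drawn inside each turn and optional
#' highlighted spans (e.g. unusually long spontaneous discussions).
#'
#' @param turns Turn table from [build_turns()].
#' @param pitch_z Optional normalized pitch from [zscore_by_speaker()].
#' @param highlights Optional data frame `start`, `end` of spans to shade.
#' @return A ggplot object (deterministic for fixed input).
#' @export
turn_at_talk <- function(turns, pitch_z = NULL, highlights = NULL) {
  seg <- turn_at_talk_segments(turns)
  half <- 0.35
  p <- ggplot2::ggplot(seg)
  if (!is.null(highlights) && nrow(highlights))
    p <- p + ggplot2::geom_rect(
      data = highlights,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "yellow", alpha = 0.25,
      inherit.aes = FALSE)
  p <- p + ggplot2::geom_rect(
    ggplot2::aes(xmin = .data$start, xmax = .data$end,
                 ymin = .data$lane - half, ymax = .data$lane + half,
                 fill = .data$color)) +
    ggplot2::scale_fill_identity()
  if (!is.null(pitch_z)) {
    tr <- pitch_z[!is.na(pitch_z$z) & !is.na(pitch_z$speaker), , drop = FALSE]
    lanes <- unique(seg[, c("speaker", "lane")])
    tr$lane <- lanes$lane[match(tr$speaker, lanes$speaker)]
    tr <- tr[!is.na(tr$lane), , drop = FALSE]
    zc <- pmax(pmin(tr$z, 3), -3) / 3 * half
    tr$y <- tr$lane + zc
    p <- p + ggplot2::geom_line(
      data = tr,
      ggplot2::aes(x = .data$time, y = .data$y, group = .data$speaker),
      linewidth = 0.2, color = "white")
  }
  lanes <- unique(seg[, c("speaker", "lane")])
  p + ggplot2::scale_y_continuous(breaks = lanes$lane, labels = lanes$speaker) +
    ggplot2::labs(x = "session time (s)", y = NULL,
                  title = "Turn-at-talk") +
    ggplot2::theme_minimal()
}
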