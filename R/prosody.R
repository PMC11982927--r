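#' Per-speaker Z-score normalization of a tier
#'
#' Removes anatomical and recording-setup baselines before speakers are
#' compared: each pitch/intensity point falling inside a speaker's turns is
#' transformed to `(value - mean_speaker) / sd_speaker`, where the mean and
#' standard deviation are taken over all of that speaker's in-turn points in
#' the session. Points outside every turn are attributed to no speaker and
#' left unnormalized (`z = NA`); speakers with fewer than two points, or with
#' zero spread, cannot be normalized and their points are marked missing
#' (the zero-spread case additionally warns).
#'
#' Turn spans are treated as closed intervals: points at exactly `start` or
#' `end` belong to the turn.
#'
#' @param series An [tier()].
#' @param turns Turn table from [build_turns()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A data frame `time`, `value`, `speaker` (NA outside any turn),
#'   `z` (NA where unattributable or not normalizable), with the tier's
#'   `kind`/`session_id` attributes preserved.
#' @export
zscore_by_speaker <- function(series, turns, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  out <- data.frame(time = series$time, value = series$value,
                    speaker = NA_character_, z = NA_real_)
  for (i in seq_len(nrow(turns))) {
    inside <- out$time >= turns$start[i] & out$time <= turns$end[i]
    clash <- inside & !is.na(out$speaker) & out$speaker != turns$speaker[i]
    if (any(clash))
      stop("point(s) attributable to two speakers (overlapping turns of ",
           out$speaker[clash][1], " and ", turns$speaker[i], ")", call. = FALSE)
    out$speaker[inside] <- turns$speaker[i]
  }
  for (sp in unique(out$speaker[!is.na(out$speaker)])) {
    idx <- which(out$speaker == sp)
    v <- out$value[idx]
    if (length(v) < 2L) next
    m <- mean(v)
    s <- if (sd_type == "sample") stats::sd(v) else sqrt(mean((v - m)^2))
    if (!is.finite(s) || s == 0) {
      warning("speaker ", sp, " has zero spread; points left missing",
              call. = FALSE)
      next
    }
    out$z[idx] <- (v - m) / s
  }
  attr(out, "kind") <- attr(series, "kind")
  attr(out, "session_id") <- attr(series, "session_id")
  out
}

.feat_cols <- c("mean_pitch", "max_pitch", "min_pitch",
                "mean_intensity", "max_intensity", "min_intensity")

#' Turn-level prosodic features
#'
#' For each turn, the mean, maximum and minimum of the Z-normalized pitch and
#' intensity points whose time falls within the turn span (closed interval):
#' six features per turn. A signal with no points in the span (e.g. a fully
#' unvoiced turn for pitch) yields `NA` for that signal's three features;
#' such turns are later dropped pairwise from proximity computation.
#'
#' @param turns Turn table from [build_turns()].
#' @param pitch_z,intensity_z Normalized tiers from [zscore_by_speaker()].
#' @return `turns` with columns `mean_pitch`, `max_pitch`, `min_pitch`,
#'   `mean_intensity`, `max_intensity`, `min_intensity` appended.
#' @export
turn_prosody <- function(turns, pitch_z, intensity_z) {
  one <- function(zser, s, e) {
    z <- zser$z[zser$time >= s & zser$time <= e]
    z <- z[!is.na(z)]
    if (!length(z)) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(z), max(z), min(z))
  }
  p <- t(vapply(seq_len(nrow(turns)),
                function(i) one(pitch_z, turns$start[i], turns$end[i]),
                numeric(3)))
  q <- t(vapply(seq_len(nrow(turns)),
                function(i) one(intensity_z, turns$start[i], turns$end[i]),
                numeric(3)))
  turns$mean_pitch <- p[, 1]; turns$max_pitch <- p[, 2]; turns$min_pitch <- p[, 3]
  turns$mean_intensity <- q[, 1]; turns$max_intensity <- q[, 2]
  turns$min_intensity <- q[, 3]
  turns
}
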