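# Fixture builders and independent oracles used across the suite.

# turn table built directly (no diarization round-trip); feature columns
# optional via ...
make_turns <- function(speaker, start, end, ...) {
  out <- data.frame(speaker = speaker, group = speaker_group(speaker),
                    start = start, end = end, speech = end - start)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# turns where all six prosodic features share one value vector
make_prosody_turns <- function(speaker, start, end, feature_values) {
  make_turns(speaker, start, end,
             mean_pitch = feature_values, max_pitch = feature_values,
             min_pitch = feature_values, mean_intensity = feature_values,
             max_intensity = feature_values, min_intensity = feature_values)
}

# independent OLS oracle: closed-form normal equations
ne_ols <- function(X, y) {
  Xi <- cbind(1, X)
  as.vector(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

# brute-force interval overlap length
overlap_len <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

# fine-grid occupancy oracle for window time features
grid_occupancy <- function(turns, ws, we, step = 0.001) {
  mids <- seq(ws + step / 2, we, by = step)
  cover <- rep(FALSE, length(mids))
  gtime <- c(host = 0, control = 0, participant = 0)
  for (g in names(gtime)) {
    hit <- rep(FALSE, length(mids))
    tg <- turns[turns$group == g, , drop = FALSE]
    for (i in seq_len(nrow(tg)))
      hit <- hit | (mids >= tg$start[i] & mids <= tg$end[i])
    gtime[g] <- sum(hit) * step
  }
  for (i in seq_len(nrow(turns)))
    cover <- cover | (mids >= turns$start[i] & mids <= turns$end[i])
  list(group_time = gtime, silence = 1 - sum(cover) / length(mids))
}

# random non-overlapping turn set on [0, len]
random_turns <- function(n, len, speakers = c("H", "C", "F1", "M2")) {
  cuts <- sort(runif(2 * n, 0, len))
  starts <- cuts[seq(1, 2 * n, by = 2)]
  ends <- cuts[seq(2, 2 * n, by = 2)]
  keep <- ends - starts > 1e-3
  make_turns(sample(speakers, sum(keep), replace = TRUE),
             starts[keep], ends[keep])
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal long-dialect TextGrid with one interval tier
textgrid_fixture <- function(starts, ends, labels) {
  c('File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    paste0("xmax = ", max(ends)),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    '        name = "speakers"',
    "        xmin = 0",
    paste0("        xmax = ", max(ends)),
    paste0("        intervals: size = ", length(starts)),
    unlist(lapply(seq_along(starts), function(i) c(
      paste0("        intervals [", i, "]:"),
      paste0("            xmin = ", starts[i]),
      paste0("            xmax = ", ends[i]),
      paste0('            text = "', labels[i], '"')))))
}

# reference coded-event sheet (one session's opening events)
table1_csv <- function() {
  c("topic,start_s,end_s,social,humor,game,cue,affirm,disclose,correct,nonverbal,number,host1,host2,host3,score_r1",
    "Boggle intro,0,36,0,0,1,1,0,0,0,0,1,1,0,0,1",
    "Boggle set up,37,80,0,0,1,1,1,0,0,0,4,1,0,0,2",
    "\"Boggle, set, go!\",179,1739,1,1,1,1,1,0,1,1,7,1,0,0,5",
    "Sign off,1740,1763,1,1,0,0,1,0,0,1,8,1,0,0,5")
}
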