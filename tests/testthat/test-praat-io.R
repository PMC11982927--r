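test_that("pitch tiers read identically from both Praat dialects", {
  x <- tier(c(0, 0.5), c(100, 120), kind = "pitch")
  for (fmt in c("short", "long")) {
    f <- tempfile(fileext = ".PitchTier")
    write_tier(x, f, format = fmt)
    got <- read_pitch_tier(f)
    expect_equal(got$time, c(0, 0.5))
    expect_equal(got$value, c(100, 120))
    expect_identical(attr(got, "kind"), "pitch")
  }
})

test_that("an empty tier is accepted and round-trips", {
  x <- tier(numeric(0), numeric(0), kind = "pitch")
  f <- tempfile()
  write_tier(x, f)
  got <- read_pitch_tier(f)
  expect_equal(nrow(got), 0L)
})

test_that("write-then-read is the identity on random valid tiers", {
  set.seed(11)
  for (k in 1:5) {
    n <- sample(1:40, 1)
    t0 <- sort(runif(n, 0, 100))
    t0 <- t0[!duplicated(t0)]
    x <- tier(t0, runif(length(t0), 60, 300), kind = "pitch")
    y <- tier(t0, runif(length(t0), -10, 80), kind = "intensity")
    fmt <- sample(c("short", "long"), 1)
    fx <- tempfile(); fy <- tempfile()
    write_tier(x, fx, fmt); write_tier(y, fy, fmt)
    expect_equal(as.data.frame(read_pitch_tier(fx)), as.data.frame(x))
    expect_equal(as.data.frame(read_intensity_tier(fy)), as.data.frame(y))
  }
})

test_that("intensity admits non-positive dB values but pitch does not", {
  f <- tempfile()
  write_tier(tier(c(0, 1), c(60, 55), kind = "intensity"), f)
  got <- read_intensity_tier(f)
  expect_equal(got$value, c(60, 55))
  expect_silent(tier(0.2, -5, kind = "intensity"))
  expect_error(tier(0.2, -5, kind = "pitch"), "> 0")
  expect_error(tier(c(0, 0), c(100, 110), kind = "pitch"),
               "strictly increasing")
})

test_that("malformed tier headers are rejected with the offending line", {
  f <- write_lines_tmp(c("File type = \"ooTextFile\"", "nonsense"))
  expect_error(read_pitch_tier(f), "line 2")
  f2 <- write_lines_tmp(c("not praat", "at all"))
  expect_error(read_pitch_tier(f2), "line 1")
  f3 <- write_lines_tmp(c("File type = \"ooTextFile\"",
                          "Object class = \"IntensityTier\"", "", "0", "1", "1",
                          "0", "70"))
  expect_error(read_pitch_tier(f3), "PitchTier")
})

test_that("diarization TSV and TextGrid forms normalize to one interval table", {
  s <- c(0, 2, 4, 6, 8, 10)
  e <- c(2, 4, 6, 8, 10, 12)
  lab <- c("H", "C", "F1", "M2", "N", "SO")
  f <- tempfile()
  write_diarization(data.frame(start = s, end = e, label = lab), f)
  got <- read_diarization(f)
  expect_equal(nrow(got), 6L)
  expect_equal(as.vector(table(got$label)[lab]), rep(1L, 6))

  tg <- write_lines_tmp(textgrid_fixture(s, e, lab), ".TextGrid")
  got2 <- read_diarization(tg)
  expect_equal(got2$label, lab)
  expect_equal(got2$start, s)
})

test_that("empty TextGrid labels are dropped and bad labels rejected", {
  tg <- write_lines_tmp(textgrid_fixture(c(0, 2, 5), c(2, 5, 7),
                                         c("H", "", "F1")), ".TextGrid")
  got <- read_diarization(tg)
  expect_equal(got$label, c("H", "F1"))

  f <- tempfile()
  writeLines("0\t1\tX3", f)
  expect_error(read_diarization(f), "X3")
  f2 <- tempfile()
  writeLines("5\t5\tH", f2)
  expect_error(read_diarization(f2), "end <= start")
})

test_that("the reference event sheet parses field-for-field", {
  f <- write_lines_tmp(table1_csv(), ".csv")
  ev <- read_event_sheet(f)
  expect_equal(nrow(ev), 4L)
  go <- ev[ev$topic == "Boggle, set, go!", ]
  expect_equal(go$start, 179)
  expect_equal(go$end, 1739)
  expect_equal(unlist(go[c("social", "humor", "game", "cue", "affirm",
                           "disclose", "correct", "nonverbal")],
                      use.names = FALSE),
               c(1, 1, 1, 1, 1, 0, 1, 1))
  expect_equal(go$number, 7)
  expect_equal(unlist(go[c("host1", "host2", "host3")], use.names = FALSE),
               c(1, 0, 0))
  expect_equal(go$score_r1, 5)
  intro <- ev[ev$topic == "Boggle intro", ]
  expect_equal(c(intro$start, intro$end, intro$number, intro$score_r1),
               c(0, 36, 1, 1))
  expect_equal(host_id(ev), rep(1L, 4))
})

test_that("event sheets validate scores, flags and schema", {
  bad <- table1_csv()
  bad[2] <- sub(",1$", ",6", bad[2])
  expect_error(read_event_sheet(write_lines_tmp(bad, ".csv")), "1..5")

  drop_col <- sapply(strsplit(table1_csv(), ","), function(p)
    paste(p[-4], collapse = ","))
  expect_error(read_event_sheet(write_lines_tmp(drop_col, ".csv")), "missing")

  f <- write_lines_tmp(table1_csv(), ".csv")
  ev <- read_event_sheet(f)
  f2 <- tempfile(fileext = ".csv")
  write_event_sheet(ev, f2)
  expect_equal(as.data.frame(read_event_sheet(f2)), as.data.frame(ev))
})
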