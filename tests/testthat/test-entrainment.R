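test_that("sequential pairs keep consecutive cross-speaker turns", {
  tt <- make_turns(c("H", "F1", "H"), c(0, 10, 20), c(5, 15, 25))
  pr <- sequential_pairs(tt)
  expect_equal(pr$i, c(1, 2))
  expect_equal(pr$j, c(2, 3))

  tt2 <- make_turns(c("H", "H", "F1"), c(0, 10, 20), c(5, 15, 25))
  pr2 <- sequential_pairs(tt2)
  expect_equal(pr2$i, 2)
  pr2a <- sequential_pairs(tt2, pairs = "all")
  expect_equal(nrow(pr2a), 2)

  expect_equal(nrow(sequential_pairs(tt[1, , drop = FALSE])), 0)
})

test_that("sequential pairs equal a brute-force adjacent-index filter", {
  set.seed(51)
  for (k in 1:20) {
    n <- sample(2:12, 1)
    labs <- sample(c("H", "C", "F1", "M2"), n, replace = TRUE)
    tt <- make_turns(labs, seq_len(n) * 10, seq_len(n) * 10 + 5)
    pr <- sequential_pairs(tt)
    manual <- which(labs[-n] != labs[-1])
    expect_equal(pr$i, manual)
    expect_equal(pr$j, manual + 1L)
  }
})

test_that("proximity is zero for identical features and matches the worked mean", {
  tt <- make_prosody_turns(c("H", "F1", "H"), c(0, 10, 20), c(5, 15, 25),
                           feature_values = c(0.7, 0.7, 0.7))
  p <- event_proximity(tt, 0, 30)
  expect_equal(p$d_mean_pitch, 0)
  expect_equal(p$d_min_int, 0)
  expect_equal(p$status, "ok")

  tt2 <- make_prosody_turns(c("H", "F1", "H"), c(0, 10, 20), c(5, 15, 25),
                            feature_values = c(0.5, -0.5, 1.0))
  p2 <- event_proximity(tt2, 0, 30)
  expect_equal(p2$d_mean_pitch, 1.25)
  expect_equal(p2$n_mean_pitch, 2L)
})

test_that("proximity equals an independent recomputation on random fixtures", {
  set.seed(53)
  for (k in 1:15) {
    n <- sample(3:10, 1)
    labs <- sample(c("H", "C", "F1", "M2"), n, replace = TRUE)
    vals <- rnorm(n)
    tt <- make_prosody_turns(labs, seq_len(n) * 10, seq_len(n) * 10 + 6, vals)
    p <- event_proximity(tt, 0, n * 10 + 10)
    idx <- which(labs[-n] != labs[-1])
    if (length(unique(labs)) < 2) {
      expect_equal(p$status, "single_speaker")
    } else if (!length(idx)) {
      expect_equal(p$status, "no_pairs")
    } else {
      expect_equal(p$d_mean_pitch, mean(abs(vals[idx + 1] - vals[idx])),
                   tolerance = 1e-12)
    }
  }
})

test_that("missing features drop pairwise per feature, not per event", {
  tt <- make_prosody_turns(c("H", "F1", "H"), c(0, 10, 20), c(5, 15, 25),
                           feature_values = c(1, 2, 4))
  tt$mean_pitch[2] <- NA  # unvoiced middle turn: pitch gone, intensity kept
  p <- event_proximity(tt, 0, 30)
  expect_equal(p$n_mean_pitch, 0L)
  expect_true(is.na(p$d_mean_pitch))
  expect_equal(p$d_mean_int, mean(c(1, 2)))
  expect_equal(p$n_mean_int, 2L)
})

test_that("proximity is invariant to common shifts and global sign flips", {
  set.seed(57)
  labs <- c("H", "F1", "M2", "H", "F1")
  vals <- rnorm(5)
  tt <- make_prosody_turns(labs, 0:4 * 10, 0:4 * 10 + 6, vals)
  base <- event_proximity(tt, 0, 60)
  shifted <- event_proximity(
    make_prosody_turns(labs, 0:4 * 10, 0:4 * 10 + 6, vals + 3.7), 0, 60)
  flipped <- event_proximity(
    make_prosody_turns(labs, 0:4 * 10, 0:4 * 10 + 6, -vals), 0, 60)
  expect_equal(base$d_mean_pitch, shifted$d_mean_pitch, tolerance = 1e-12)
  expect_equal(base$d_mean_pitch, flipped$d_mean_pitch, tolerance = 1e-12)
})

test_that("moving one turn away from its neighbors never lowers proximity", {
  for (eps in c(0.1, 0.5, 2)) {
    vals <- c(0.2, 1.0, 0.4)  # middle above both neighbors
    tt0 <- make_prosody_turns(c("H", "F1", "H"), c(0, 10, 20), c(5, 15, 25),
                              vals)
    tt1 <- make_prosody_turns(c("H", "F1", "H"), c(0, 10, 20), c(5, 15, 25),
                              vals + c(0, eps, 0))
    expect_gte(event_proximity(tt1, 0, 30)$d_mean_pitch,
               event_proximity(tt0, 0, 30)$d_mean_pitch)
  }
})

test_that("single-speaker events are excluded with counts, not errors", {
  tt <- rbind(
    make_prosody_turns(c("H", "F1"), c(0, 10), c(5, 15), c(1, 2)),
    make_prosody_turns(c("H", "H"), c(100, 110), c(105, 115), c(1, 2)),
    make_prosody_turns(c("F1", "M2"), c(200, 210), c(205, 215), c(0, 1)))
  ev <- data.frame(start = c(0, 100, 200), end = c(20, 120, 220))
  prox <- event_proximity_table(ev, tt)
  flt <- filter_entrainment_events(prox)
  expect_equal(unname(flt$counts["kept"]), 2L)
  expect_equal(unname(flt$counts["excluded_single_speaker"]), 1L)
  expect_equal(nrow(flt$kept), 2L)

  # all single-speaker: empty subset, counts still reported
  ev2 <- data.frame(start = 100, end = 120)
  flt2 <- filter_entrainment_events(event_proximity_table(ev2, tt))
  expect_equal(nrow(flt2$kept), 0L)
  expect_equal(unname(flt2$counts["excluded_single_speaker"]), 1L)
})
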