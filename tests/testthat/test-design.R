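test_that("recognizable pattern predicate flags ramps and alternations", {
  expect_true(is_recognizable_pattern(c(1, 2, 3, 4, 5)))
  expect_true(is_recognizable_pattern(c(1, 2, 1, 2, 1)))
  expect_true(is_recognizable_pattern(c(1, 2, 4, 6, 8)))
  expect_true(is_recognizable_pattern(c(9, 7, 5, 3, 1)))
  expect_false(is_recognizable_pattern(c(1, 9, 4, 3, 6)))
  expect_false(is_recognizable_pattern(c(2, 7, 3, 9, 1)))
  expect_error(is_recognizable_pattern(c(1, 2, 3)), "5 digits")
  expect_true(is_recognizable_pattern(c(3, 1, 4, 1, 5),
                                      blacklist = list(c(3, 1, 4, 1, 5))))
})

test_that("generated sequences satisfy all invariants across many seeds", {
  set.seed(1)
  n_bad <- 0L
  for (i in 1:2500) {
    s <- generate_sequence(i)
    stopifnot(length(s$targets) == 5L)
    if (any(diff(s$targets) == 0L)) n_bad <- n_bad + 1L
    if (is_recognizable_pattern(s$targets)) n_bad <- n_bad + 1L
    glen <- lengths(s$gaps)
    if (sum(glen) != 5L || any(glen > 2L)) n_bad <- n_bad + 1L
    if (any(stats::na.omit(unlist(s$gaps)) %in% c(0L, 10L))) n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
})

test_that("sequence generation is deterministic under a fixed seed", {
  a <- generate_sequence(1, seed = 99)
  b <- generate_sequence(1, seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("schedules satisfy the pseudo-randomization constraints", {
  seqs <- generate_sequences(seed = 4)
  for (seed in 1:100) {
    sch <- build_schedule(seqs, seed = seed)
    expect_equal(nrow(sch), 120L)
    expect_true(all(table(sch$sequence_id, sch$condition) == 1L))
    expect_false(any(sch$condition[-1] == sch$condition[-120]))
    min_gap <- min(vapply(split(seq_len(120), sch$sequence_id),
                          function(ix) min(diff(ix)), numeric(1)))
    expect_gte(min_gap, 3)
  }
  expect_identical(build_schedule(seqs, seed = 5),
                   build_schedule(seqs, seed = 5))
})

test_that("rhythmic timelines sit on the 1250 ms grid with 5 induction events", {
  seqs <- generate_sequences(n = 5, seed = 12)
  for (cond in c("C_2-VisRhythmSupp", "C_4-AVRhythmSupp")) {
    for (s in seqs) {
      tl <- render_timeline(cond, s, seed = s$id)
      tg <- tl$onset_ms[tl$kind == "target"]
      expect_equal(unique(diff(tg)), 1250L)
      ind <- tl[tl$kind == "induction", ]
      expect_equal(nrow(ind), 5L)
      expect_true(all(diff(ind$onset_ms) == 1250L))
      expect_lt(max(ind$onset_ms), min(tg))
      # induction shares the target grid
      expect_true(all((tg[1] - ind$onset_ms) %% 1250L == 0L))
      # tones only with audio support, co-onset with targets
      expect_equal(all(tl$has_tone[tl$kind == "target"]),
                   cond == "C_4-AVRhythmSupp")
    }
  }
})

test_that("non-rhythmic timelines place exactly one target per 1250 ms window", {
  seqs <- generate_sequences(n = 5, seed = 13)
  cfg <- design_config()
  for (cond in c("C_1-NoSupp", "C_3-AudSupp")) {
    for (s in seqs) {
      tl <- render_timeline(cond, s, seed = 100 + s$id)
      expect_equal(sum(tl$kind == "induction"), 0L)
      tg <- tl$onset_ms[tl$kind == "target"]
      w <- (tg - cfg$fixation_ms) %/% 1250L
      expect_identical(as.integer(w), 0:4)
      expect_equal(all(tl$has_tone[tl$kind == "target"]), cond == "C_3-AudSupp")
    }
  }
})

test_that("every trial presents 10 digit stimuli without overlap", {
  seqs <- generate_sequences(n = 8, seed = 21)
  conds <- conditions()$code
  for (s in seqs) {
    for (cond in conds) {
      tl <- render_timeline(cond, s, seed = s$id * 7)
      digits <- tl[tl$kind %in% c("target", "distractor"), ]
      expect_equal(nrow(digits), 10L)
      # non-overlap of digit events
      digits <- digits[order(digits$onset_ms), ]
      expect_true(all(diff(digits$onset_ms) >= digits$duration_ms[-10]))
      # answer window of 7 s closes the trial
      aw <- tl[tl$kind == "answer_window", ]
      expect_equal(aw$duration_ms, 7000L)
      expect_equal(aw$onset_ms, max(tl$onset_ms))
      # fixation brackets the digit stream
      fx <- tl[tl$kind == "fixation", ]
      expect_equal(nrow(fx), 2L)
      expect_lt(fx$onset_ms[1], min(digits$onset_ms))
    }
  }
})

test_that("pre-test schedule is balanced with bounded runs", {
  for (seed in 1:25) {
    ps <- build_pretest_schedule(seed = seed)
    expect_equal(nrow(ps), 108L)
    expect_identical(which(ps$is_practice), 1:12)
    key <- paste(ps$modality, ps$object)
    expect_true(all(table(key) == 18L))
    expect_true(all(table(key[1:12]) == 2L))
    runs <- rle(key)
    expect_lte(max(runs$lengths), 4L)
  }
  expect_identical(build_pretest_schedule(seed = 3),
                   build_pretest_schedule(seed = 3))
})
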