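test_that("participant sampling matches the configured marginals", {
  cfg <- sim_config(n_participants = 5000L)
  pp <- sample_participants(cfg, seed = 91)
  expect_equal(nrow(pp), 5000L)
  expect_true(all(pp$Age >= 18 & pp$Age <= 30))
  expect_equal(mean(pp$Age), 23.71, tolerance = 0.15)
  expect_equal(mean(pp$MusEducation), 28 / 41, tolerance = 0.03)
  expect_equal(mean(pp$dominance_latent == "AUD"), 0.5, tolerance = 0.02)
  # trait-covariate links have the configured signs
  expect_lt(cor(pp$PercTaskDifficulty, pp$encode_base), -0.3)
  expect_gt(cor(pp$PercSoundSupport, pp$audio_gain), 0.3)
  expect_lt(cor(pp$PercTiredness, pp$learning_slope), -0.3)
  # zero-variance config collapses the traits
  cfg0 <- sim_config(n_participants = 10L, intercept_sd = 0, audio_gain_sd = 0,
                     rhythm_gain_sd = 0, slope_sd = 0, intrusion_sd = 0)
  pp0 <- sample_participants(cfg0, seed = 92)
  expect_equal(length(unique(pp0$encode_base)), 1L)
  expect_equal(length(unique(pp0$audio_gain)), 1L)
})

test_that("pre-test simulation realizes the planted dominance structure", {
  cfg <- sim_config()
  ps <- build_pretest_schedule(seed = 93)
  big <- do.call(rbind, replicate(30, ps, simplify = FALSE))
  big$index <- seq_len(nrow(big))
  big$is_practice <- FALSE
  pp <- sample_participants(sim_config(n_participants = 2L), seed = 94)
  pp$dominance_latent <- c("VIS", "AUD")
  for (j in 1:2) {
    rec <- simulate_pretest(pp[j, ], big, cfg, seed = 95 + j)
    expect_true(all(rec$rt_ms > 0))
    keep <- rec$correct & rec$rt_ms <= 1500
    mm <- tapply(rec$rt_ms[keep], rec$modality[keep], mean)
    if (pp$dominance_latent[j] == "VIS") expect_lt(mm["Vi"], mm["Au"])
    else expect_lt(mm["Au"], mm["Vi"])
    expect_lt(mm["AV"], min(mm["Au"], mm["Vi"]))
  }
  # the lapse mechanism produces material for the cleaning stage
  rec <- simulate_pretest(pp[1, ], big, cfg, seed = 98)
  expect_gt(sum(rec$rt_ms > 1500), 0)
})

test_that("recall simulation honours its noiseless limits", {
  sq <- generate_sequence(1, seed = 96)
  prof <- data.frame(encode_base = 50, audio_gain = 0, rhythm_gain = 0,
                     learning_slope = 0, intrusion_rate = 0)
  cfg <- sim_config(substitution_rate = 0, deletion_rate = 0)
  set.seed(97)
  ans <- simulate_recall(prof, "C_1-NoSupp", sq, 60, cfg)
  expect_identical(ans, sq$targets)
  expect_equal(per_digit_score(sq$targets, ans), 1)
  prof$encode_base <- -50
  ans0 <- simulate_recall(prof, "C_1-NoSupp", sq, 60, cfg)
  expect_identical(ans0, integer(0))
  expect_equal(per_digit_score(sq$targets, ans0), 0)
})

test_that("audio support lowers the distraction score in simulation", {
  set.seed(99)
  cfg <- sim_config(substitution_rate = 0, deletion_rate = 0)
  prof <- data.frame(encode_base = 0.4, audio_gain = 0.5, rhythm_gain = 0,
                     learning_slope = 0, intrusion_rate = 0.25)
  sq <- generate_sequence(2, seed = 100)
  stream <- presented_stream(sq)
  score_cond <- function(cond, nrep) {
    mean(vapply(seq_len(nrep), function(i) {
      a <- simulate_recall(prof, cond, sq, 60, cfg)
      if (length(a) == 0) return(0)
      distraction_score(sq$targets, stream, a)
    }, numeric(1)))
  }
  d1 <- score_cond("C_1-NoSupp", 1500)
  d3 <- score_cond("C_3-AudSupp", 1500)
  expect_lt(d3, d1)
})

test_that("a full study bundle has the right shape and is reproducible", {
  cfg <- sim_config(n_participants = 4L,
                    design = design_config(n_sequences = 8L))
  b1 <- simulate_study(cfg, seed = 5)
  expect_equal(nrow(b1$answers), 4L * 8L * 4L)
  expect_equal(length(b1$sequences), 8L)
  expect_true(all(grepl("^[1-9]*$", b1$answers$answer)))
  # every participant sees every (sequence, condition) pair once
  for (p in unique(b1$answers$participant)) {
    sub <- b1$answers[b1$answers$participant == p, ]
    expect_true(all(table(sub$sequence_id, sub$condition) == 1L))
  }
  b2 <- simulate_study(cfg, seed = 5)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- simulate_study(cfg, seed = 6)
  expect_false(identical(b1$answers$answer, b3$answers$answer))
})

test_that("score_study produces the modelling dataset with covariates", {
  cfg <- sim_config(n_participants = 6L,
                    design = design_config(n_sequences = 6L))
  b <- simulate_study(cfg, seed = 7)
  sc <- score_study(b)
  expect_equal(nrow(sc), 6L * 24L)
  expect_true(all(c("per_digit", "levenshtein", "distraction", "Dominance",
                    "NoiseSensitivity", "PercSoundSupport", "Participant",
                    "Order", "Condition", "Sequence") %in% names(sc)))
  expect_true(all(sc$per_digit >= 0 & sc$per_digit <= 1))
  expect_true(all(sc$distraction >= -1 & sc$distraction <= 1))
  expect_true(all(table(sc$participant) == 24L))
})
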