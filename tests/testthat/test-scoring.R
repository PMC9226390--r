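test_that("per-digit score reproduces the published worked examples", {
  expect_equal(per_digit_score(c(1, 9, 4, 3, 6), c(1, 9, 4, 6)), 0.8)
  expect_equal(per_digit_score(c(1, 9, 4, 3, 6), c(1, 2, 9, 4, 3, 6)), 5 / 6)
  expect_equal(per_digit_score(c(1, 9, 4, 3, 6), c(1, 9, 4, 3, 6)), 1)
  expect_equal(per_digit_score(c(1, 9, 4, 3, 6), c(5, 2, 1, 8, 7)), 0)
  expect_equal(per_digit_score(c(1, 9, 4, 3, 6), integer(0)), 0)
})

test_that("per-digit DP equals brute-force dummy placement on random pairs", {
  set.seed(101)
  for (i in 1:1000) {
    a <- rand_digits(7, 1)
    b <- rand_digits(7, 0)
    expect_equal(per_digit_score(a, b), per_digit_brute(a, b))
  }
})

test_that("levenshtein matches naive recursion and utils::adist", {
  expect_equal(levenshtein(c(1, 9, 4, 3, 6), c(1, 9, 4, 3, 6)), 0)
  expect_equal(levenshtein(c(1, 9, 4, 3, 6), c(1, 9, 4, 6)), 1)
  expect_equal(levenshtein(c(1, 9, 4, 3, 6), c(9, 4, 3, 6, 1)), 2)
  set.seed(202)
  for (i in 1:200) {
    a <- rand_digits(6)
    b <- rand_digits(6)
    d <- levenshtein(a, b)
    expect_equal(d, lev_recursive(a, b))
    expect_identical(
      d,
      as.integer(utils::adist(paste(a, collapse = ""), paste(b, collapse = ""))[1, 1]))
  }
})

test_that("levenshtein satisfies the metric axioms", {
  set.seed(303)
  for (i in 1:200) {
    a <- rand_digits(6)
    b <- rand_digits(6)
    cvec <- rand_digits(6)
    expect_equal(levenshtein(a, a), 0L)
    expect_equal(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, cvec), levenshtein(a, b) + levenshtein(b, cvec))
    if (!identical(a, b)) expect_gt(levenshtein(a, b), 0L)
  }
})

test_that("distraction score reproduces the published worked examples", {
  expect_equal(
    distraction_score(c(1, 9, 4, 3, 6), c(1, 2, 9, 2, 3, 4, 3, 6, 2),
                      c(1, 9, 4, 3, 6)), -0.8)
  expect_equal(
    distraction_score(c(2, 9, 3, 8, 5), c(2, 9, 8, 1, 3, 8, 5, 6),
                      c(2, 9, 8, 5, 6)), 0.6)
})

test_that("distraction score is bounded and uses n groups for n >= 2", {
  # all five groups match targets, none match the alternating stream
  expect_equal(
    distraction_score(c(1, 9, 4, 3, 6), c(1, 5, 9, 5, 4, 5, 3, 5, 6),
                      c(1, 9, 4, 3, 6)), -1)
  set.seed(404)
  for (i in 1:300) {
    tg <- rand_digits(5, 5)
    pres <- sample(c(tg, sample(1:9, 4, replace = TRUE)))
    ans <- rand_digits(7, 1)
    d <- distraction_score(tg, pres, ans)
    expect_gte(d, -1)
    expect_lte(d, 1)
    n <- length(ans)
    # group count = answer length: score * n is an integer in [-n, n]
    if (n >= 2) expect_equal(d * n, round(d * n))
  }
  # degenerate answers
  expect_equal(distraction_score(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), 7), 0)
  expect_error(distraction_score(c(1, 2, 3), integer(0), c(1, 2)),
               "non-empty")
})

test_that("two-digit answers count the prefix and suffix pair once each", {
  # answer "19": prefix of targets (countT = 1), no match in the stream
  expect_equal(distraction_score(c(1, 9, 4, 3, 6), c(1, 2, 9, 4, 3, 6, 2),
                                 c(1, 9)), (0 - 1) / 2)
})

test_that("transcripts normalize to digit vectors", {
  expect_identical(normalize_answer(" 1 9-4,36 "), c(1L, 9L, 4L, 3L, 6L))
  expect_identical(normalize_answer(""), integer(0))
  expect_warning(out <- normalize_answer("1904"), "0")
  expect_identical(out, c(1L, 9L, 4L))
})

test_that("score_trial assembles all three scores with blank handling", {
  sq <- structure(list(id = 1L, targets = c(1L, 9L, 4L, 3L, 6L),
                       gaps = list(2L, c(2L, 3L), integer(0), integer(0),
                                   c(2L, NA_integer_))),
                  class = "trial_sequence")
  expect_identical(presented_stream(sq), c(1L, 2L, 9L, 2L, 3L, 4L, 3L, 6L, 2L))
  b <- score_trial(sq, "19436")
  expect_equal(b$per_digit, 1)
  expect_equal(b$levenshtein, 0L)
  expect_equal(b$distraction, -0.8)
  e <- score_trial(sq, "")
  expect_equal(e$per_digit, 0)
  expect_equal(e$levenshtein, 5L)
  expect_equal(e$distraction, 0)
})

test_that("batch scorer joins answers with sequences", {
  seqs <- generate_sequences(n = 3, seed = 77)
  ans <- data.frame(participant = "P01", order = 1:3,
                    condition = "C_1-NoSupp", sequence_id = c(2L, 1L, 3L),
                    answer = vapply(c(2L, 1L, 3L), function(i)
                      paste(seqs[[i]]$targets, collapse = ""), character(1)))
  out <- score_answers(ans, seqs)
  expect_equal(out$per_digit, rep(1, 3))
  expect_equal(out$levenshtein, rep(0, 3))
})
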