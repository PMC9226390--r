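toy_scored <- function() {
  # 4 participants x 4 sequences x 4 conditions, planted audio benefit
  set.seed(81)
  d <- expand.grid(participant = c("P1", "P2", "P3", "P4"), sequence_id = 1:4,
                   condition = conditions()$code, stringsAsFactors = FALSE)
  cc <- conditions()
  audio <- cc$audio_support[match(d$condition, cc$code)]
  d$score <- round(runif(nrow(d)), 2) + 0.4 * audio
  d
}

test_that("kruskal-wallis matches stats::kruskal.test and hand ranks", {
  d <- data.frame(condition = rep(c("A", "B", "C"), each = 4),
                  s = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  r <- kruskal_conditions(d, "s")
  # no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  rbar <- c(2.5, 6.5, 10.5)
  H <- 12 / (12 * 13) * sum(4 * (rbar - 6.5)^2)
  expect_equal(r$statistic, H)
  expect_equal(r$df, 2)
  expect_equal(r$p, pchisq(H, 2, lower.tail = FALSE))
  ident <- data.frame(condition = rep(c("A", "B"), 5), s = 1)
  expect_warning(r0 <- kruskal_conditions(ident, "s"), "identical")
  expect_equal(r0$p, 1)
})

test_that("paired wilcoxon matches the exact signed-rank distribution", {
  d <- data.frame(
    participant = rep("P1", 8), sequence_id = rep(1:4, 2),
    condition = rep(c("A", "B"), each = 4),
    s = c(1, 2, 3, 5, 2, 4, 6, 9))
  r <- wilcoxon_paired(d, "s", "A", "B")
  w <- wilcox.test(c(1, 2, 3, 5), c(2, 4, 6, 9), paired = TRUE, exact = TRUE)
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p, w$p.value)
  # exhaustive enumeration oracle for the exact p-value: all sign flips
  dd <- c(1, 2, 3, 5) - c(2, 4, 6, 9)
  rk <- rank(abs(dd))
  V <- sum(rk[dd > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 4)))
  Vs <- signs %*% rk
  p_exact <- 2 * min(mean(Vs <= V), mean(Vs >= V))
  expect_equal(r$p, min(1, p_exact))
})

test_that("degenerate paired comparisons warn and return p = 1", {
  d <- data.frame(participant = "P1", sequence_id = rep(1:4, 2),
                  condition = rep(c("A", "B"), each = 4), s = 1:4)
  expect_warning(r <- wilcoxon_paired(d, "s", "A", "B"), "zero")
  expect_equal(r$p, 1)
  expect_error(wilcoxon_paired(d[1:4, ], "s", "A", "B"), "pairs")
})

test_that("post-hoc matrix covers all six pairs symmetrically", {
  d <- toy_scored()
  pm <- posthoc_matrix(d, "score")
  expect_equal(nrow(pm), 6L)
  r_ab <- wilcoxon_paired(d, "score", "C_1-NoSupp", "C_3-AudSupp")
  r_ba <- wilcoxon_paired(d, "score", "C_3-AudSupp", "C_1-NoSupp")
  expect_equal(r_ab$p, r_ba$p)
  pm_h <- posthoc_matrix(d, "score", adjust = "holm")
  expect_true(all(pm_h$p_adj >= pm_h$p))
})

test_that("subgroup contrasts split, test within and between", {
  set.seed(82)
  d <- toy_scored()
  cov_map <- c(P1 = 1, P2 = 2, P3 = 4, P4 = 5)
  d$PercSoundSupport <- cov_map[d$participant]
  out <- subgroup_contrasts(d, "score", "PercSoundSupport")
  expect_true(all(c("disturbing", "supporting") %in% out$within$subgroup))
  expect_equal(nrow(out$between), 4L)
  # degenerate subgroup flagged
  d$PercSoundSupport <- 5
  d$PercSoundSupport[d$participant == "P1"] <- 0
  expect_warning(
    expect_warning(subgroup_contrasts(d[d$participant == "P1", ], "score",
                                      "PercSoundSupport"), "fewer than 2"),
    "fewer than 2")
})

test_that("the text report lists the omnibus and all pairwise lines", {
  d <- toy_scored()
  kw <- kruskal_conditions(d, "score")
  pm <- posthoc_matrix(d, "score")
  rep_lines <- format_results_report("per_digit", kw, pm)
  expect_length(rep_lines, 2L + 6L)
  expect_match(rep_lines[1], "per_digit")
  expect_match(rep_lines[2], "Kruskal-Wallis")
})

test_that("noise-sensitivity clustering separates planted groups", {
  set.seed(83)
  lo <- matrix(rnorm(50, 2, 0.7), 10, 5)
  hi <- matrix(rnorm(50, 8, 0.7), 10, 5)
  items <- rbind(lo, hi)
  lab <- cluster_noise_sensitivity(items, seed = 1)
  expect_identical(as.character(lab),
                   rep(c("tolerant", "sensitive"), each = 10))
  # order invariance
  perm <- sample(20)
  lab2 <- cluster_noise_sensitivity(items[perm, ], seed = 1)
  expect_identical(as.character(lab2), as.character(lab)[perm])
  expect_error(cluster_noise_sensitivity(matrix(5, 8, 5)), "identical")
})
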