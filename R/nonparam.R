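#' Kruskal-Wallis omnibus test across conditions
#'
#' Rank-based H statistic (tie-corrected) comparing a score across the four
#' presentation conditions at trial level.
#'
#' @param data scored dataset (one row per trial) with a condition column.
#' @param score name of the score column.
#' @param condition name of the condition column.
#' @return data.frame with \code{statistic}, \code{df}, \code{p}, \code{n},
#'   \code{method}.
#' @export
kruskal_conditions <- function(data, score, condition = "condition") {
  x <- data[[score]]
  gcol <- factor(data[[condition]])
  if (nlevels(gcol) < 2L) stop("need at least 2 conditions")
  if (stats::var(x) == 0) {
    warning("all score values identical; returning H = 0, p = 1")
    return(data.frame(statistic = 0, df = nlevels(gcol) - 1L, p = 1,
                      n = length(x), method = "Kruskal-Wallis"))
  }
  kt <- stats::kruskal.test(x, gcol)
  data.frame(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value, n = length(x), method = "Kruskal-Wallis")
}

#' Paired Wilcoxon signed-rank test between two conditions
#'
#' Pairs observations by (participant, sequence): each sequence is seen by
#' each participant once per condition, so the same items are measured under
#' both conditions. Zero differences are dropped; the exact distribution is
#' used for 25 or fewer non-zero pairs without ties, otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param data scored dataset.
#' @param score score column name.
#' @param cond_a,cond_b condition codes to compare.
#' @param participant,sequence,condition column names of the pairing keys.
#' @return data.frame \code{statistic}, \code{p}, \code{n} (non-zero pairs),
#'   \code{method}.
#' @export
wilcoxon_paired <- function(data, score, cond_a, cond_b,
                            participant = "participant",
                            sequence = "sequence_id",
                            condition = "condition") {
  da <- data[data[[condition]] == cond_a, c(participant, sequence, score)]
  db <- data[data[[condition]] == cond_b, c(participant, sequence, score)]
  key_a <- paste(da[[participant]], da[[sequence]])
  key_b <- paste(db[[participant]], db[[sequence]])
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("no complete (participant, sequence) pairs")
  xa <- da[[score]][match(common, key_a)]
  xb <- db[[score]][match(common, key_b)]
  d <- xa - xb
  nz <- sum(d != 0)
  if (nz == 0L) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(data.frame(statistic = 0, p = 1, n = 0L,
                      method = "Wilcoxon signed rank"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(xa, xb, paired = TRUE, exact = nz <= 25L,
                       correct = TRUE))
  data.frame(statistic = unname(wt$statistic), p = wt$p.value, n = nz,
             method = "Wilcoxon signed rank")
}

#' All pairwise condition comparisons
#'
#' Paired Wilcoxon tests for all condition pairs. Raw p-values are reported
#' by default (no multiplicity correction); Holm adjustment is available.
#'
#' @inheritParams wilcoxon_paired
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return data.frame with one row per unordered pair.
#' @export
posthoc_matrix <- function(data, score, adjust = c("none", "holm"),
                           participant = "participant",
                           sequence = "sequence_id",
                           condition = "condition") {
  adjust <- match.arg(adjust)
  lev <- sort(unique(as.character(data[[condition]])))
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    r <- wilcoxon_paired(data, score, pairs[1, i], pairs[2, i],
                         participant, sequence, condition)
    cbind(data.frame(cond_a = pairs[1, i], cond_b = pairs[2, i],
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  rownames(out) <- NULL
  out
}

#' Subgroup condition contrasts
#'
#' Splits participants into two groups on a questionnaire covariate and
#' repeats the pairwise condition comparisons within each subgroup, plus a
#' between-subgroup unpaired rank-sum test within each condition. Preset
#' split rules: \code{"midpoint"} dichotomizes a 0-5 scale at its midpoint
#' (\code{<= 2.5} low, labelled \code{"disturbing"} for perceived-support
#' scales vs \code{"supporting"}); \code{"upper_third"} splits easy/medium
#' (\code{< 4}) versus hard (\code{>= 4}). A function mapping covariate
#' values to a two-level factor may be supplied instead.
#'
#' @inheritParams wilcoxon_paired
#' @param split_covariate covariate column (constant within participant).
#' @param split_rule \code{"midpoint"}, \code{"upper_third"}, or a function.
#' @return list with \code{within} (pairwise tests per subgroup) and
#'   \code{between} (subgroup comparison per condition); degenerate
#'   subgroups (fewer than 2 participants) are flagged with \code{NA} tests.
#' @export
subgroup_contrasts <- function(data, score, split_covariate,
                               split_rule = "midpoint",
                               participant = "participant",
                               sequence = "sequence_id",
                               condition = "condition") {
  v <- data[[split_covariate]]
  grp <- if (is.function(split_rule)) {
    factor(split_rule(v))
  } else if (identical(split_rule, "midpoint")) {
    factor(ifelse(v <= 2.5, "disturbing", "supporting"),
           levels = c("disturbing", "supporting"))
  } else if (identical(split_rule, "upper_third")) {
    factor(ifelse(v < 4, "easy_medium", "hard"),
           levels = c("easy_medium", "hard"))
  } else stop("unknown split_rule")
  data$.subgroup <- grp
  within <- list()
  for (gl in levels(grp)) {
    sub <- data[data$.subgroup == gl, , drop = FALSE]
    np <- length(unique(sub[[participant]]))
    if (np < 2L) {
      warning("subgroup '", gl, "' has fewer than 2 participants; flagged")
      within[[gl]] <- NULL
      next
    }
    pm <- posthoc_matrix(sub, score, "none", participant, sequence, condition)
    pm$subgroup <- gl
    within[[gl]] <- pm
  }
  lev <- sort(unique(as.character(data[[condition]])))
  between <- lapply(lev, function(cc) {
    sub <- data[data[[condition]] == cc, , drop = FALSE]
    g1 <- sub[[score]][sub$.subgroup == levels(grp)[1]]
    g2 <- sub[[score]][sub$.subgroup == levels(grp)[2]]
    if (!length(g1) || !length(g2)) {
      return(data.frame(condition = cc, statistic = NA_real_, p = NA_real_,
                        n = length(g1) + length(g2),
                        method = "Wilcoxon rank sum"))
    }
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                              correct = TRUE))
    data.frame(condition = cc, statistic = unname(wt$statistic),
               p = wt$p.value, n = length(g1) + length(g2),
               method = "Wilcoxon rank sum")
  })
  list(within = do.call(rbind, within), between = do.call(rbind, between),
       split = table(grp[!duplicated(data[[participant]])]))
}

#' Text report of the condition-level analysis
#'
#' Formats the omnibus and pairwise results of one score as a plain-text
#' summary: the Kruskal-Wallis line followed by one line per condition
#' contrast.
#'
#' @param score score name (label only).
#' @param kw result of [kruskal_conditions()].
#' @param posthoc result of [posthoc_matrix()].
#' @return character vector of report lines.
#' @export
format_results_report <- function(score, kw, posthoc) {
  lines <- c(
    sprintf("Score: %s", score),
    sprintf("  Overall difference across conditions (Kruskal-Wallis, p = %.2g)",
            kw$p))
  for (i in seq_len(nrow(posthoc))) {
    lines <- c(lines, sprintf(
      "  %s vs %s: %ssignificant (Wilcoxon, p = %.2g)",
      posthoc$cond_a[i], posthoc$cond_b[i],
      if (posthoc$p[i] < 0.05) "" else "not ", posthoc$p[i]))
  }
  lines
}

#' Noise-sensitivity clustering from questionnaire items
#'
#' 2-means clustering of the five-item noise-sensitivity short-form vectors
#' (0-10 response scale); the cluster with the higher mean item score is
#' labelled \code{"sensitive"}, the other \code{"tolerant"}.
#'
#' @param items numeric matrix or data.frame, one row per participant,
#'   columns the five item responses.
#' @param seed optional seed for restarts.
#' @param n_restarts k-means restarts.
#' @return factor of labels, one per row.
#' @export
cluster_noise_sensitivity <- function(items, seed = NULL, n_restarts = 20L) {
  m <- as.matrix(items)
  if (nrow(unique(m)) < 2L) stop("all item vectors identical; cannot cluster")
  km <- with_seed(seed,
    stats::kmeans(m, centers = 2L, nstart = n_restarts, iter.max = 100L))
  hi <- which.max(rowMeans(km$centers))
  factor(ifelse(km$cluster == hi, "sensitive", "tolerant"),
         levels = c("tolerant", "sensitive"))
}
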