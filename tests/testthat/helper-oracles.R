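# Independent brute-force oracles used to validate the scoring algorithms.

# PerDigit by exhaustive enumeration of all dummy placements: choose the
# positions of the long string occupied by the short string's symbols.
per_digit_brute <- function(targets, answer) {
  nt <- length(targets)
  na <- length(answer)
  if (na == 0L) return(0)
  if (nt == na) return(mean(targets == answer))
  long <- if (nt >= na) targets else answer
  short <- if (nt >= na) answer else targets
  best <- 0L
  for (pos in utils::combn(length(long), length(short), simplify = FALSE)) {
    best <- max(best, sum(long[pos] == short))
  }
  best / length(long)
}

# Levenshtein by naive exponential recursion (lengths <= 6).
lev_recursive <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(lev_recursive(a[-1], b) + 1L,
      lev_recursive(a, b[-1]) + 1L,
      lev_recursive(a[-1], b[-1]) + (a[1] != b[1]))
}

rand_digits <- function(max_len = 7, min_len = 0) {
  n <- sample(min_len:max_len, 1)
  if (n == 0) integer(0) else sample(1:9, n, replace = TRUE)
}

# small helper: scored dataset with audio/rhythm indicators attached
add_condition_indicators <- function(sc) {
  cc <- conditions()
  sc$audio <- cc$audio_support[match(sc$condition, cc$code)]
  sc$rhythm <- cc$rhythmic[match(sc$condition, cc$code)]
  sc
}

# draw ordinal proportional-odds data (fixed effects + optional RE)
sim_po_data <- function(n, beta, x, thresholds, group = NULL, u = NULL) {
  eta <- drop(x %*% beta)
  if (!is.null(group)) eta <- eta + u[group]
  cum <- vapply(thresholds, function(t) stats::plogis(t - eta), numeric(n))
  yi <- rowSums(sweep(cbind(cum, 1), 1, stats::runif(n), "<")) + 1L
  factor(yi, levels = seq_len(length(thresholds) + 1L))
}
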