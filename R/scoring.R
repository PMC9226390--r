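#' Serial-recall outcome scores
#'
#' Three complementary accuracy scores for a recalled digit string measured
#' against the target sequence and, for the distraction score, against the
#' complete presented stimulus stream (targets and distractors interleaved).
#'
#' \describe{
#'   \item{PerDigit}{Positional accuracy in \code{[0, 1]}. When answer and
#'     target lengths differ, dummy symbols (matching nothing) are inserted
#'     into the shorter string so as to maximize the number of positions at
#'     which the two strings agree; the score is that maximum divided by the
#'     longer length. Equal lengths compare position by position.}
#'   \item{Levenshtein}{Unit-cost edit distance (insertion, deletion,
#'     substitution of one digit); lower is better.}
#'   \item{Distraction}{In \code{[-1, 1]}. All consecutive digit triples of
#'     the answer are looked up as contiguous substrings of (a) the target
#'     sequence and (b) the full presented stream; additionally the first two
#'     digits are tested as a prefix and the last two as a suffix of each.
#'     The score is (matches against the stream minus matches against the
#'     targets) divided by the answer length. Negative values indicate
#'     target-driven recall, positive values distractor intrusion.}
#' }
#'
#' @param targets integer vector of target digits (1-9).
#' @param answer integer vector of recalled digits (1-9), possibly empty.
#' @param presented integer vector: the full stimulus stream in presentation
#'   order with blank distractors removed.
#' @return \code{per_digit_score}: a number in \code{[0, 1]}.
#' @examples
#' per_digit_score(c(1, 9, 4, 3, 6), c(1, 9, 4, 6))        # 0.8
#' per_digit_score(c(1, 9, 4, 3, 6), c(1, 2, 9, 4, 3, 6))  # 5/6
#' levenshtein(c(1, 9, 4, 3, 6), c(1, 9, 4, 6))            # 1
#' distraction_score(c(1, 9, 4, 3, 6),
#'                   c(1, 2, 9, 2, 3, 4, 3, 6, 2),
#'                   c(1, 9, 4, 3, 6))                     # -0.8
#' @export
per_digit_score <- function(targets, answer) {
  targets <- as.integer(targets)
  answer <- as.integer(answer)
  check_digits(targets, "targets")
  check_digits(answer, "answer")
  nt <- length(targets)
  na <- length(answer)
  if (nt == 0L) stop("'targets' must be non-empty")
  if (na == 0L) return(0)
  if (nt == na) return(mean(targets == answer))
  long <- if (nt >= na) targets else answer
  short <- if (nt >= na) answer else targets
  max_positional_matches(long, short) / length(long)
}

# Maximum number of positional matches achievable by inserting
# length(long) - length(short) dummies into `short`. Equivalent to choosing
# an order-preserving injection of the short string's symbols into the long
# string's positions. DP over (short index, long position), O(nm).
max_positional_matches <- function(long, short) {
  n <- length(long)
  m <- length(short)
  # f[i, j]: best matches placing short[i..m] into long[j..n]
  f <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
  for (i in m:1L) {
    # positions j must satisfy n - j + 1 >= m - i + 1  =>  j <= n - m + i
    for (j in (n - m + i):1L) {
      place <- f[i + 1L, j + 1L] + (short[i] == long[j])
      skip <- if (j < n - m + i) f[i, j + 1L] else -1L
      f[i, j] <- max(place, skip)
    }
  }
  f[1L, 1L]
}

#' @rdname per_digit_score
#' @param a,b integer vectors to compare.
#' @return \code{levenshtein}: a non-negative integer.
#' @export
levenshtein <- function(a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  n <- length(a)
  m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' @rdname per_digit_score
#' @return \code{distraction_score}: a number in \code{[-1, 1]}.
#' @export
distraction_score <- function(targets, presented, answer) {
  targets <- as.integer(targets)
  presented <- as.integer(presented)
  answer <- as.integer(answer)
  if (length(presented) == 0L) stop("'presented' must be non-empty")
  check_digits(targets, "targets")
  check_digits(presented, "presented")
  check_digits(answer, "answer")
  n <- length(answer)
  if (n <= 1L) return(0)
  count_against <- function(ref) {
    cnt <- 0L
    if (n >= 3L) {
      for (i in seq_len(n - 2L)) {
        if (has_substring(ref, answer[i:(i + 2L)])) cnt <- cnt + 1L
      }
    }
    # edge cases: first two digits as prefix, last two as suffix
    if (length(ref) >= 2L) {
      if (all(ref[1:2] == answer[1:2])) cnt <- cnt + 1L
      if (all(ref[(length(ref) - 1L):length(ref)] == answer[(n - 1L):n]))
        cnt <- cnt + 1L
    }
    cnt
  }
  (count_against(presented) - count_against(targets)) / n
}

# contiguous-substring test for short integer vectors
has_substring <- function(hay, needle) {
  nh <- length(hay)
  nn <- length(needle)
  if (nn > nh) return(FALSE)
  for (s in 0:(nh - nn)) {
    if (all(hay[s + seq_len(nn)] == needle)) return(TRUE)
  }
  FALSE
}

check_digits <- function(x, what) {
  if (length(x) && (anyNA(x) || any(x < 1L | x > 9L)))
    stop(sprintf("'%s' must contain digits 1-9 only", what))
  invisible(x)
}

#' Normalize an answer transcript to a digit vector
#'
#' Strips whitespace, punctuation and any non-digit characters, keeping the
#' digits 1-9 in order. The character "0" is outside the stimulus alphabet
#' and is dropped with a warning.
#'
#' @param x a character string (one transcript).
#' @return integer vector of digits 1-9.
#' @export
normalize_answer <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x)) return(integer(0))
  chars <- strsplit(as.character(x), "")[[1]]
  if (any(chars == "0")) {
    warning("'0' found in transcript; digits range 1-9, dropping it")
    chars <- chars[chars != "0"]
  }
  as.integer(chars[chars %in% as.character(1:9)])
}

#' Score one trial
#'
#' Computes the three outcome scores for a recalled answer against a
#' generated trial sequence (see [generate_sequence()]). The distraction
#' score uses the sequence's presentation-order stream with blanks removed.
#'
#' @param sequence a \code{trial_sequence} object.
#' @param answer integer vector of recalled digits, or a transcript string
#'   (normalized via [normalize_answer()]).
#' @return a list with components \code{per_digit}, \code{levenshtein},
#'   \code{distraction}.
#' @export
score_trial <- function(sequence, answer) {
  stopifnot(inherits(sequence, "trial_sequence"))
  if (is.character(answer)) answer <- normalize_answer(answer)
  answer <- as.integer(answer)
  stream <- presented_stream(sequence, keep_blanks = FALSE)
  list(
    per_digit = per_digit_score(sequence$targets, answer),
    levenshtein = levenshtein(sequence$targets, answer),
    distraction = distraction_score(sequence$targets, stream, answer)
  )
}

#' Score a table of answers
#'
#' Batch scorer joining a per-trial answer table with the generated sequence
#' set. Answers are normalized from transcripts.
#'
#' @param answers data.frame with columns \code{participant}, \code{order},
#'   \code{condition}, \code{sequence_id}, \code{answer} (string).
#' @param sequences list of \code{trial_sequence} objects indexed by id.
#' @return the input data.frame with \code{per_digit}, \code{levenshtein}
#'   and \code{distraction} columns appended.
#' @export
score_answers <- function(answers, sequences) {
  need <- c("participant", "order", "condition", "sequence_id", "answer")
  if (!all(need %in% names(answers)))
    stop("answers must have columns: ", paste(need, collapse = ", "))
  ids <- vapply(sequences, function(s) s$id, integer(1))
  pd <- lev <- dis <- numeric(nrow(answers))
  for (i in seq_len(nrow(answers))) {
    sq <- sequences[[match(answers$sequence_id[i], ids)]]
    if (is.null(sq)) stop("unknown sequence_id at row ", i)
    b <- score_trial(sq, as.character(answers$answer[i]))
    pd[i] <- b$per_digit
    lev[i] <- b$levenshtein
    dis[i] <- b$distraction
  }
  answers$per_digit <- pd
  answers$levenshtein <- lev
  answers$distraction <- dis
  answers
}
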