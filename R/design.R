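#' Experimental design constants
#'
#' Default timing and count parameters of the audiovisual digit-span design:
#' 200 ms visual digits on a 1250 ms (0.8 Hz) target grid, five targets and
#' five distractors per sequence, 30 sequences crossed with four conditions
#' into 120 trials, and a 7 s oral answer window. Tone metadata (500 Hz,
#' 50 ms, 70 dB) is carried for the record; no audio is rendered.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of design parameters.
#' @export
design_config <- function(...) {
  cfg <- list(
    n_targets = 5L,
    n_distractors = 5L,
    n_sequences = 30L,
    interval_ms = 1250L,
    stim_ms = 200L,
    answer_window_ms = 7000L,
    fixation_ms = 1000L,
    n_induction = 5L,
    blank_probability = 0.1,
    blacklist = list(),
    tone_hz = 500,
    tone_ms = 50,
    level_db = 70
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown design_config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' The four presentation conditions
#'
#' @return data.frame with columns \code{code}, \code{audio_support},
#'   \code{rhythmic}; audio support in conditions 3-4, rhythmic presentation
#'   in conditions 2 and 4.
#' @export
conditions <- function() {
  data.frame(
    code = c("C_1-NoSupp", "C_2-VisRhythmSupp", "C_3-AudSupp", "C_4-AVRhythmSupp"),
    audio_support = c(FALSE, FALSE, TRUE, TRUE),
    rhythmic = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

condition_info <- function(code) {
  cc <- conditions()
  i <- match(code, cc$code)
  if (is.na(i)) stop("unknown condition code: ", code)
  cc[i, ]
}

#' Detect recognizable target patterns
#'
#' Target quintuples that form an obvious pattern are excluded from the
#' stimulus pool because participants could encode the rule rather than the
#' digits. A quintuple is flagged when it is (a) an arithmetic progression
#' with any constant step (including negative), (b) a strict two-value
#' alternation ABABA, or (c) a parity ladder: a monotone run climbing the
#' even or odd digits at constant step after an initial step of 1 or 2
#' (e.g. 1-2-4-6-8). An extra user blacklist of explicit quintuples is
#' honoured.
#'
#' @param targets integer vector of exactly 5 digits in 1-9.
#' @param blacklist optional list of integer vectors to exclude verbatim.
#' @return TRUE if the pattern is recognizable and must be rejected.
#' @examples
#' is_recognizable_pattern(c(1, 2, 3, 4, 5))  # TRUE
#' is_recognizable_pattern(c(1, 2, 1, 2, 1))  # TRUE
#' is_recognizable_pattern(c(1, 9, 4, 3, 6))  # FALSE
#' @export
is_recognizable_pattern <- function(targets, blacklist = list()) {
  targets <- as.integer(targets)
  if (length(targets) != 5L || anyNA(targets) || any(targets < 1L | targets > 9L))
    stop("'targets' must be exactly 5 digits in 1-9")
  d <- diff(targets)
  if (length(unique(d)) == 1L) return(TRUE)          # arithmetic progression
  if (length(unique(targets)) == 2L &&
      all(targets[c(1, 3, 5)] == targets[1]) &&
      all(targets[c(2, 4)] == targets[2])) return(TRUE)  # ABABA
  # parity ladder: constant step over 4 digits, entered/exited by a short step
  ladder <- function(v) {
    dd <- diff(v)
    head_ok <- length(unique(dd[-1])) == 1L && abs(dd[2]) <= 2 &&
      abs(dd[1]) <= 2 && sign(dd[1]) == sign(dd[2])
    tail_ok <- length(unique(dd[-4])) == 1L && abs(dd[1]) <= 2 &&
      abs(dd[4]) <= 2 && sign(dd[4]) == sign(dd[1])
    head_ok || tail_ok
  }
  if (ladder(targets)) return(TRUE)
  for (b in blacklist) {
    if (length(b) == 5L && all(as.integer(b) == targets)) return(TRUE)
  }
  FALSE
}

#' Generate one trial sequence
#'
#' Draws five target digits (uniform over 1-9, rejection-sampled until
#' consecutive targets differ and [is_recognizable_pattern()] is FALSE) and
#' five distractors spread over the five gaps that follow the targets. Gap
#' sizes are drawn uniformly from all 5-tuples in \{0,1,2\}^5 summing to 5;
#' each distractor is uniform over the nine digits and a blank token
#' (encoded \code{NA}), blank with probability \code{blank_probability}.
#'
#' @param id integer sequence identifier.
#' @param seed optional integer seed (local to this call).
#' @param config a [design_config()] list.
#' @param max_tries rejection-sampling cap for the target draw.
#' @return an object of class \code{trial_sequence}: list with \code{id},
#'   \code{targets} (5 digits) and \code{gaps} (list of 5 integer vectors,
#'   \code{NA} = blank).
#' @export
generate_sequence <- function(id, seed = NULL, config = design_config(),
                              max_tries = 10000L) {
  with_seed(seed, {
    targets <- NULL
    for (k in seq_len(max_tries)) {
      cand <- sample(1:9, config$n_targets, replace = TRUE)
      if (any(diff(cand) == 0L)) next
      if (is_recognizable_pattern(cand, config$blacklist)) next
      targets <- cand
      break
    }
    if (is.null(targets)) stop("target rejection sampling exceeded max_tries")
    profile <- sample_gap_profile(config$n_targets, config$n_distractors)
    probs <- c(rep((1 - config$blank_probability) / 9, 9), config$blank_probability)
    gaps <- lapply(profile, function(m) {
      if (m == 0L) return(integer(0))
      vals <- sample(c(1:9, NA_integer_), m, replace = TRUE, prob = probs)
      as.integer(vals)
    })
    structure(list(id = as.integer(id), targets = targets, gaps = gaps),
              class = "trial_sequence")
  })
}

# uniform draw from integer tuples in {0,1,2}^n summing to `total`
sample_gap_profile <- function(n, total) {
  space <- gap_profile_space(n, total)
  space[[sample.int(length(space), 1L)]]
}

.gap_cache <- new.env(parent = emptyenv())

gap_profile_space <- function(n, total) {
  key <- paste(n, total)
  if (!is.null(.gap_cache[[key]])) return(.gap_cache[[key]])
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  keep <- rowSums(grid) == total
  out <- lapply(which(keep), function(i) as.integer(grid[i, ]))
  .gap_cache[[key]] <- out
  out
}

#' @rdname generate_sequence
#' @param n number of sequences (default from config).
#' @return \code{generate_sequences}: list of \code{trial_sequence}.
#' @export
generate_sequences <- function(n = NULL, seed = NULL, config = design_config()) {
  n <- n %||% config$n_sequences
  with_seed(seed, lapply(seq_len(n), function(i)
    generate_sequence(i, seed = NULL, config = config)))
}

#' Presentation-order stimulus stream of a sequence
#'
#' @param sequence a \code{trial_sequence}.
#' @param keep_blanks keep blank distractors (as \code{NA}) in the stream?
#' @return integer vector: targets and distractors interleaved in
#'   presentation order.
#' @export
presented_stream <- function(sequence, keep_blanks = FALSE) {
  out <- integer(0)
  for (i in seq_along(sequence$targets)) {
    out <- c(out, sequence$targets[i], sequence$gaps[[i]])
  }
  if (!keep_blanks) out <- out[!is.na(out)]
  out
}

#' @export
print.trial_sequence <- function(x, ...) {
  gap_str <- vapply(x$gaps, function(g) {
    if (!length(g)) return("-")
    paste(ifelse(is.na(g), "_", g), collapse = "")
  }, character(1))
  cat(sprintf("Trial sequence %d: targets %s; gaps %s\n",
              x$id, paste(x$targets, collapse = ""),
              paste(gap_str, collapse = ",")))
  invisible(x)
}

#' Build the pseudo-randomized 120-trial schedule
#'
#' Each of the 30 sequences is crossed with the four conditions (120 slots).
#' The order is randomized under two constraints: adjacent trials never share
#' a condition, and at least two other sequences intervene before a sequence
#' is repeated. A randomized greedy pass with restarts is used; it fails with
#' an error if \code{max_tries} restarts are exhausted.
#'
#' @param sequences list of \code{trial_sequence} (defines the sequence ids).
#' @param seed optional integer seed.
#' @param max_tries restart cap for the constraint-satisfaction search.
#' @return data.frame with columns \code{order} (1..120), \code{condition},
#'   \code{sequence_id}.
#' @export
build_schedule <- function(sequences, seed = NULL, max_tries = 2000L) {
  ids <- vapply(sequences, function(s) s$id, integer(1))
  conds <- conditions()$code
  pairs <- expand.grid(sequence_id = ids, condition = conds,
                       stringsAsFactors = FALSE)
  n <- nrow(pairs)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      remaining <- rep(TRUE, n)
      cond_out <- character(n)
      seq_out <- integer(n)
      ok <- TRUE
      for (pos in seq_len(n)) {
        recent <- if (pos > 1L) seq_out[max(1L, pos - 2L):(pos - 1L)] else integer(0)
        cond_ok <- if (pos == 1L) TRUE else pairs$condition != cond_out[pos - 1L]
        feas <- which(remaining & cond_ok & !(pairs$sequence_id %in% recent))
        if (!length(feas)) { ok <- FALSE; break }
        pick <- feas[sample.int(length(feas), 1L)]
        cond_out[pos] <- pairs$condition[pick]
        seq_out[pos] <- pairs$sequence_id[pick]
        remaining[pick] <- FALSE
      }
      if (ok) {
        return(data.frame(order = seq_len(n), condition = cond_out,
                          sequence_id = seq_out, stringsAsFactors = FALSE))
      }
    }
    stop("schedule constraint satisfaction failed after ", max_tries, " restarts")
  })
}

#' Render the stimulus timeline of one trial
#'
#' Lays the trial's digits out in time. Visual digits last 200 ms. In the
#' rhythmic conditions, target onsets sit on an exact 1250 ms grid preceded
#' by five induction events on the same grid (visual circles without audio
#' support, tone bursts with). In the non-rhythmic conditions each target is
#' jittered uniformly inside its own 1250 ms window subject to fitting that
#' window's distractors after it without overlap. Distractors always land at
#' a random moment inside the residual interval of their gap. A fixation
#' event opens and closes the digit stream and a 7 s answer window ends the
#' trial. Tones (metadata only) co-onset with targets in audio conditions.
#'
#' @param condition a condition code (see [conditions()]).
#' @param sequence a \code{trial_sequence}.
#' @param seed optional integer seed.
#' @param config a [design_config()] list.
#' @return data.frame of events: \code{onset_ms}, \code{duration_ms},
#'   \code{kind} (fixation/induction/target/distractor/answer_window),
#'   \code{digit} (NA for blanks and non-digit events), \code{has_tone}.
#' @export
render_timeline <- function(condition, sequence, seed = NULL,
                            config = design_config()) {
  info <- condition_info(condition)
  iv <- config$interval_ms
  sms <- config$stim_ms
  fix <- config$fixation_ms
  nt <- length(sequence$targets)
  with_seed(seed, {
    ev <- list()
    add <- function(onset, dur, kind, digit = NA_integer_, tone = FALSE) {
      ev[[length(ev) + 1L]] <<- data.frame(
        onset_ms = as.integer(round(onset)), duration_ms = as.integer(dur),
        kind = kind, digit = digit, has_tone = tone, stringsAsFactors = FALSE)
    }
    add(0, fix, "fixation")
    if (info$rhythmic) {
      for (i in seq_len(config$n_induction)) {
        onset <- fix + (i - 1L) * iv
        if (info$audio_support) add(onset, config$tone_ms, "induction", tone = TRUE)
        else add(onset, sms, "induction")
      }
      t0 <- fix + config$n_induction * iv
      target_onsets <- t0 + (seq_len(nt) - 1L) * iv
      for (i in seq_len(nt)) {
        add(target_onsets[i], sms, "target", sequence$targets[i],
            tone = info$audio_support)
        gap <- sequence$gaps[[i]]
        if (length(gap)) {
          lo <- target_onsets[i] + sms
          hi <- t0 + i * iv
          onsets <- pack_events(lo, hi, length(gap), sms)
          for (k in seq_along(gap))
            add(onsets[k], sms, "distractor", gap[k])
        }
      }
      seq_end <- t0 + nt * iv
    } else {
      t0 <- fix
      for (i in seq_len(nt)) {
        wlo <- t0 + (i - 1L) * iv
        whi <- t0 + i * iv
        gap <- sequence$gaps[[i]]
        m <- 1L + length(gap)
        onsets <- pack_events(wlo, whi, m, sms)
        add(onsets[1L], sms, "target", sequence$targets[i],
            tone = info$audio_support)
        for (k in seq_along(gap))
          add(onsets[k + 1L], sms, "distractor", gap[k])
      }
      seq_end <- t0 + nt * iv
    }
    add(seq_end, fix, "fixation")
    add(seq_end + fix, config$answer_window_ms, "answer_window")
    out <- do.call(rbind, ev)
    out <- out[order(out$onset_ms, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# place m non-overlapping events of duration `dur` uniformly at random in
# [lo, hi), preserving draw order; returns onsets
pack_events <- function(lo, hi, m, dur) {
  slack <- (hi - lo) - m * dur
  if (slack < 0) stop("infeasible packing: ", m, " events of ", dur,
                      " ms in ", hi - lo, " ms")
  cuts <- sort(stats::runif(m, 0, slack))
  lo + cuts + (seq_len(m) - 1L) * dur
}

#' Build the 108-trial audiovisual dominance pre-test schedule
#'
#' Six stimulus types (modality Au/Vi/AV crossed with object A/B) are
#' presented 18 times each over 108 trials. The first 12 trials are practice
#' with exactly two of each type. No more than four identical stimuli may
#' occur in a row.
#'
#' @param seed optional integer seed.
#' @param max_tries restart cap.
#' @return data.frame with columns \code{index} (1..108), \code{modality},
#'   \code{object}, \code{is_practice}.
#' @export
build_pretest_schedule <- function(seed = NULL, max_tries = 2000L) {
  types <- expand.grid(modality = c("Au", "Vi", "AV"), object = c("A", "B"),
                       stringsAsFactors = FALSE)
  key <- paste(types$modality, types$object)
  with_seed(seed, {
    draw_block <- function(counts, prev_tail) {
      n <- sum(counts)
      out <- integer(n)
      left <- counts
      hist <- prev_tail
      for (pos in seq_len(n)) {
        feas <- which(left > 0L)
        # forbid extending a run of 4 identical stimuli
        if (length(hist) >= 4L && length(unique(utils::tail(hist, 4L))) == 1L)
          feas <- setdiff(feas, utils::tail(hist, 1L))
        if (!length(feas)) return(NULL)
        pick <- feas[sample.int(length(feas), 1L)]
        out[pos] <- pick
        left[pick] <- left[pick] - 1L
        hist <- c(hist, pick)
      }
      out
    }
    for (try in seq_len(max_tries)) {
      practice <- draw_block(rep(2L, 6L), integer(0))
      if (is.null(practice)) next
      main <- draw_block(rep(16L, 6L), practice)
      if (is.null(main)) next
      idx <- c(practice, main)
      return(data.frame(
        index = seq_along(idx),
        modality = types$modality[idx],
        object = types$object[idx],
        is_practice = seq_along(idx) <= 12L,
        stringsAsFactors = FALSE))
    }
    stop("pre-test schedule constraint satisfaction failed after ",
         max_tries, " restarts")
  })
}
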