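#' Simulation configuration
#'
#' Defaults describe the study the analysis pipeline is designed for:
#' 41 participants performing 120 trials (30 sequences x 4 conditions), a
#' positive auditory-support effect (log-odds 0.3 on target encoding and on
#' distractor rejection), a null rhythm effect, a learning trend over trial
#' order that is heterogeneous across participants, and a 108-trial
#' reaction-time pre-test with a planted audiovisual-dominance split.
#'
#' @param ... named overrides of any default.
#' @return a named list (class \code{sim_config}).
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_participants = 41L,
    # recall model (logit scale unless noted)
    encode_base_mean = 0.4,       # mean per-target encoding log-odds
    intercept_sd = 0.7,           # participant random intercept SD
    audio_logor = 0.3,            # planted auditory-support effect
    audio_gain_sd = 0.3,          # between-participant spread of that effect
    rhythm_logor = 0,             # planted rhythm effect (null)
    rhythm_gain_sd = 0,
    learning_slope_mean = 0.25,   # logit change from trial 60 to 120
    slope_sd = 0.2,               # participant random slope SD
    intrusion_base = 0.15,        # distractor intrusion probability
    intrusion_sd = 0.3,           # participant spread, logit scale
    substitution_rate = 0.05,     # recalled digit replaced at random
    deletion_rate = 0.02,         # encoded digit dropped at recall
    # pre-test reaction-time model (ms; RT = shift + lognormal)
    rt_shift = 200,
    rt_meanlog_dom = log(150),    # dominant modality
    rt_meanlog_nondom = log(220),
    rt_sdlog = 0.25,
    rt_participant_sd = 0.08,     # overall-speed jitter, log scale
    av_facilitation = 0.15,       # multisensory benefit, log scale
    pretest_error_rate = 0.03,
    pretest_lapse_rate = 0.01,    # slow outliers beyond the 1500 ms cutoff
    design = design_config()
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$intrusion_base >= 0, cfg$intrusion_base <= 1,
            cfg$substitution_rate >= 0, cfg$substitution_rate <= 1,
            cfg$deletion_rate >= 0, cfg$deletion_rate <= 1,
            cfg$intercept_sd >= 0, cfg$slope_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Sample participant profiles
#'
#' Draws observed covariates and the latent traits that drive the recall and
#' reaction-time simulators. Marginals mirror the target population: age
#' normal 23.71 (SD 2.69) truncated to 18-30, sexes roughly balanced, music
#' education in about 28/41, handedness 36 right / 5 left, and a roughly
#' even auditory/visual dominance split. Questionnaire covariates are
#' deterministic-plus-noise functions of the latent traits so that subgroup
#' analyses have structure to find: perceived task difficulty falls with
#' encoding ability, perceived sound support rises with the participant's
#' audio gain, perceived rhythm support with the rhythm gain, and perceived
#' tiredness falls with the learning slope.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return data.frame, one row per participant, holding covariates
#'   (\code{Sex}, \code{Age}, ..., \code{NSS1}-\code{NSS5}) and latent
#'   traits (\code{encode_base}, \code{audio_gain}, \code{rhythm_gain},
#'   \code{learning_slope}, \code{intrusion_rate}, \code{dominance_latent}).
#' @export
sample_participants <- function(config = sim_config(), seed = NULL) {
  n <- config$n_participants
  with_seed(seed, {
    age <- round(clamp(stats::rnorm(n, 23.71, 2.69), 18, 30))
    six <- function(x) clamp(round(x), 0, 5)
    encode_base <- config$encode_base_mean + stats::rnorm(n, 0, config$intercept_sd)
    audio_gain <- config$audio_logor + stats::rnorm(n, 0, config$audio_gain_sd)
    rhythm_gain <- config$rhythm_logor + stats::rnorm(n, 0, config$rhythm_gain_sd)
    learning_slope <- config$learning_slope_mean + stats::rnorm(n, 0, config$slope_sd)
    intrusion_rate <- stats::plogis(stats::qlogis(config$intrusion_base) +
                                      stats::rnorm(n, 0, config$intrusion_sd))
    dominance <- sample(rep(c("AUD", "VIS"), length.out = n))
    noise_latent <- clamp(stats::rnorm(n, 5, 2), 0, 10)
    nss <- sapply(1:5, function(i) clamp(round(noise_latent + stats::rnorm(n, 0, 1)), 0, 10))
    colnames(nss) <- paste0("NSS", 1:5)
    zscore <- function(x) if (stats::sd(x) < 1e-12) x * 0 else (x - mean(x)) / stats::sd(x)
    d <- data.frame(
      participant = sprintf("P%02d", seq_len(n)),
      Sex = sample(rep(c("F", "M"), length.out = n)),
      Age = age,
      Handedness = sample(c("L", "R"), n, replace = TRUE, prob = c(5, 36) / 41),
      MusActive = stats::runif(n) < 0.4,
      MusEducation = stats::runif(n) < 28 / 41,
      MValence = round(clamp(stats::rnorm(n, 6, 2), 0, 10), 1),
      MArousal = round(clamp(stats::rnorm(n, 5, 2), 0, 10), 1),
      Activity = sample(1:5, n, replace = TRUE),
      Caffeine = stats::runif(n) < 0.5,
      PercTiredness = six(2.5 - 1.2 * zscore(learning_slope) + stats::rnorm(n, 0, 0.9)),
      PercMemoryDifficulty = six(stats::rnorm(n, 2.5, 1.2)),
      PercTaskDifficulty = six(2.5 - 1.4 * zscore(encode_base) + stats::rnorm(n, 0, 0.8)),
      PercRhythmSupport = six(2.5 + 1.4 * zscore(rhythm_gain) + stats::rnorm(n, 0, 0.8)),
      PercSoundSupport = six(2.5 + 1.4 * zscore(audio_gain) + stats::rnorm(n, 0, 0.8)),
      stringsAsFactors = FALSE)
    d <- cbind(d, nss)
    d$encode_base <- encode_base
    d$audio_gain <- audio_gain
    d$rhythm_gain <- rhythm_gain
    d$learning_slope <- learning_slope
    d$intrusion_rate <- intrusion_rate
    d$dominance_latent <- dominance
    d$rt_speed <- stats::rnorm(n, 0, config$rt_participant_sd)
    d
  })
}

#' Simulate the dominance pre-test for one participant
#'
#' Reaction times are shift + lognormal with a shorter log-mean in the
#' participant's dominant modality and an audiovisual log-mean equal to the
#' unimodal minimum minus a multisensory facilitation. A small error rate
#' and occasional slow lapses (beyond the 1500 ms cleaning cutoff) are
#' injected so the cleaning stage has work to do.
#'
#' @param profile one row of [sample_participants()] output.
#' @param schedule a pre-test schedule from [build_pretest_schedule()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return data.frame of pre-test records for this participant.
#' @export
simulate_pretest <- function(profile, schedule, config = sim_config(),
                             seed = NULL) {
  with_seed(seed, {
    dom_vis <- profile$dominance_latent == "VIS"
    ml <- c(
      Au = if (dom_vis) config$rt_meanlog_nondom else config$rt_meanlog_dom,
      Vi = if (dom_vis) config$rt_meanlog_dom else config$rt_meanlog_nondom)
    ml <- ml + profile$rt_speed
    ml["AV"] <- min(ml) - config$av_facilitation
    n <- nrow(schedule)
    rt <- config$rt_shift +
      stats::rlnorm(n, ml[schedule$modality], config$rt_sdlog)
    lapse <- stats::runif(n) < config$pretest_lapse_rate
    rt[lapse] <- stats::runif(sum(lapse), 1501, 2500)
    data.frame(
      participant = profile$participant,
      index = schedule$index,
      modality = schedule$modality,
      object = schedule$object,
      is_practice = schedule$is_practice,
      rt_ms = round(rt, 1),
      correct = stats::runif(n) >= config$pretest_error_rate,
      stringsAsFactors = FALSE)
  })
}

#' Simulate one recalled answer
#'
#' Each of the five targets is encoded independently with probability
#' \code{plogis(encode_base + audio_gain * audio + rhythm_gain * rhythmic +
#' learning_slope * (order - 60)/60)}; each non-blank distractor intrudes
#' with the participant's intrusion rate, reduced on the logit scale by the
#' audio gain under auditory support (audio helps reject distractors).
#' Recalled items are emitted in presentation order; encoded items may be
#' dropped (deletion) or replaced by a uniform random digit (substitution).
#' Blanks are never recalled.
#'
#' @param profile one participant row.
#' @param condition a condition code.
#' @param sequence a \code{trial_sequence}.
#' @param order trial rank 1..120.
#' @param config a [sim_config()].
#' @return integer vector of recalled digits (possibly empty).
#' @export
simulate_recall <- function(profile, condition, sequence, order,
                            config = sim_config()) {
  info <- condition_info(condition)
  lp <- profile$encode_base +
    profile$audio_gain * info$audio_support +
    profile$rhythm_gain * info$rhythmic +
    profile$learning_slope * (order - 60) / 60
  p_enc <- stats::plogis(lp)
  p_int <- stats::plogis(stats::qlogis(profile$intrusion_rate) -
                           profile$audio_gain * info$audio_support)
  out <- integer(0)
  for (i in seq_along(sequence$targets)) {
    if (stats::runif(1) < p_enc) out <- c(out, sequence$targets[i])
    for (dg in sequence$gaps[[i]]) {
      if (!is.na(dg) && stats::runif(1) < p_int) out <- c(out, dg)
    }
  }
  if (length(out) && config$deletion_rate > 0) {
    out <- out[stats::runif(length(out)) >= config$deletion_rate]
  }
  if (length(out) && config$substitution_rate > 0) {
    sub <- stats::runif(length(out)) < config$substitution_rate
    out[sub] <- sample(1:9, sum(sub), replace = TRUE)
  }
  out
}

#' Simulate a complete study
#'
#' Generates 30 shared sequences, an independent pseudo-randomized 120-trial
#' schedule per participant (all participants see the same sequences in
#' different orders), recalled answers, dominance pre-test logs and the
#' covariate table — everything the downstream scoring, clustering,
#' nonparametric and model-ladder stages consume. Fully reproducible from
#' \code{seed}.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; per-component sub-seeds are derived
#'   from it.
#' @return list (class \code{study_bundle}) with elements \code{sequences},
#'   \code{participants}, \code{schedules}, \code{answers},
#'   \code{pretest}, \code{config}, \code{seed}.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  sequences <- generate_sequences(seed = sub_seed(seed, 1L),
                                  config = config$design)
  participants <- sample_participants(config, seed = sub_seed(seed, 2L))
  n <- nrow(participants)
  schedules <- vector("list", n)
  answers <- vector("list", n)
  pretest <- vector("list", n)
  for (j in seq_len(n)) {
    prof <- participants[j, ]
    sched <- build_schedule(sequences, seed = sub_seed(seed, 100L + j))
    sched$participant <- prof$participant
    schedules[[j]] <- sched[, c("participant", "order", "condition", "sequence_id")]
    ps <- build_pretest_schedule(seed = sub_seed(seed, 300L + j))
    pretest[[j]] <- simulate_pretest(prof, ps, config,
                                     seed = sub_seed(seed, 500L + j))
    ans <- with_seed(sub_seed(seed, 700L + j), {
      vapply(seq_len(nrow(sched)), function(t) {
        sq <- sequences[[sched$sequence_id[t]]]
        paste(simulate_recall(prof, sched$condition[t], sq, sched$order[t],
                              config), collapse = "")
      }, character(1))
    })
    answers[[j]] <- data.frame(
      participant = prof$participant,
      order = sched$order,
      condition = sched$condition,
      sequence_id = sched$sequence_id,
      answer = ans,
      stringsAsFactors = FALSE)
  }
  structure(list(
    sequences = sequences,
    participants = participants,
    schedules = do.call(rbind, schedules),
    answers = do.call(rbind, answers),
    pretest = do.call(rbind, pretest),
    config = config,
    seed = seed), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study bundle: %d participants, %d sequences, ",
                     "%d answer rows, %d pre-test rows (seed %s)\n"),
              nrow(x$participants), length(x$sequences), nrow(x$answers),
              nrow(x$pretest), format(x$seed)))
  invisible(x)
}

#' Score a study bundle into the analysis dataset
#'
#' Scores every answer and joins the participant covariates plus the
#' dominance label derived from the pre-test, producing the one-row-per-trial
#' dataset consumed by the nonparametric pipeline and the model ladder.
#'
#' @param bundle a [simulate_study()] bundle.
#' @param dominance_seed seed for the dominance clustering restarts.
#' @return data.frame with scores, trial descriptors and covariates
#'   (capitalized modelling names: \code{Participant}, \code{Order},
#'   \code{Condition}, \code{Sequence}, \code{Dominance}, ...).
#' @export
score_study <- function(bundle, dominance_seed = 1L) {
  scored <- score_answers(bundle$answers, bundle$sequences)
  cleaned <- clean_pretest(bundle$pretest)
  dom <- cluster_dominance(rt_profiles(cleaned), seed = dominance_seed)
  nss <- as.matrix(bundle$participants[, paste0("NSS", 1:5)])
  noise <- cluster_noise_sensitivity(nss, seed = dominance_seed)
  cov <- bundle$participants
  cov$Dominance <- dom$label[match(cov$participant, dom$participant)]
  cov$NoiseSensitivity <- as.character(noise)
  keep <- c("participant", "Sex", "Age", "Handedness", "MusActive",
            "MusEducation", "Dominance", "MValence", "MArousal", "Activity",
            "Caffeine", "NoiseSensitivity", "PercTiredness",
            "PercMemoryDifficulty", "PercTaskDifficulty",
            "PercRhythmSupport", "PercSoundSupport")
  out <- merge(scored, cov[, keep], by = "participant", sort = FALSE)
  out$Participant <- out$participant
  out$Order <- out$order
  out$Condition <- out$condition
  out$Sequence <- out$sequence_id
  out[order(out$participant, out$order), ]
}
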