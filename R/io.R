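#' Read and write pipeline artifacts
#'
#' All tabular artifacts are UTF-8 comma-separated files with a header row
#' and "." as decimal mark; nested structures (sequences, model fits) are
#' JSON. Orders and indices are 1-based.
#'
#' @name avspan-io
NULL

#' @rdname avspan-io
#' @param sequences list of \code{trial_sequence}.
#' @param path file path.
#' @export
write_sequences <- function(sequences, path) {
  obj <- lapply(sequences, function(s) list(
    id = s$id, targets = s$targets,
    gaps = lapply(s$gaps, function(g) ifelse(is.na(g), "blank", as.character(g)))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname avspan-io
#' @export
read_sequences <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(s) {
    gaps <- lapply(s$gaps, function(g) {
      v <- unlist(g, use.names = FALSE)
      if (is.null(v)) return(integer(0))
      out <- suppressWarnings(as.integer(v))
      out[v == "blank"] <- NA_integer_
      out
    })
    structure(list(id = as.integer(s$id[[1]]),
                   targets = as.integer(unlist(s$targets)),
                   gaps = gaps),
              class = "trial_sequence")
  })
}

#' @rdname avspan-io
#' @param schedule schedule data.frame.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname avspan-io
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("order", "condition", "sequence_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("schedule file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!d$condition %in% conditions()$code)
  if (length(bad)) stop("malformed condition code at row ", bad[1], ": ",
                        d$condition[bad[1]])
  d
}

#' @rdname avspan-io
#' @param timeline events data.frame from [render_timeline()].
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(timeline, path, row.names = FALSE)
  invisible(path)
}

#' @rdname avspan-io
#' @param answers answers data.frame; on read, transcripts are normalized
#'   (non-digit characters stripped) into \code{answer}.
#' @export
write_answers_csv <- function(answers, path) {
  utils::write.csv(answers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname avspan-io
#' @export
read_answers_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(answer = "character"))
  need <- c("participant", "order", "condition", "sequence_id", "answer")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("answers file missing column(s): ",
                         paste(miss, collapse = ", "))
  d$answer[is.na(d$answer)] <- ""
  d$answer <- vapply(d$answer, function(a)
    paste(normalize_answer(a), collapse = ""), character(1), USE.NAMES = FALSE)
  d
}

#' @rdname avspan-io
#' @param x generic data.frame artifact (scores, covariates, pre-test logs,
#'   test results).
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname avspan-io
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname avspan-io
#' @param fit a [cumlink()] fit.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    formula = deparse1(fit$formula),
    thresholds = as.list(fit$alpha),
    coefficients = as.list(fit$beta),
    odds_ratios = as.list(exp(fit$beta)),
    re_covariance = if (!is.null(fit$re_covariance))
      unclass(as.data.frame(fit$re_covariance)) else NULL,
    re_sd = if (!is.null(fit$re_sd)) as.list(fit$re_sd) else NULL,
    logLik = fit$logLik, aic = fit$aic, n_params = fit$n_params,
    nobs = fit$nobs, converged = fit$converged, method = fit$method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname avspan-io
#' @param ladder a [run_ladder()] result.
#' @export
write_ladder_csv <- function(ladder, path) {
  utils::write.csv(as.data.frame(ladder), path, row.names = FALSE)
  invisible(path)
}

#' Read a configuration file (YAML or JSON)
#'
#' Recognized keys mirror [design_config()] and [sim_config()] fields; the
#' file extension selects the parser.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    return(yaml::read_yaml(path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  stop("config must be .yaml, .yml or .json")
}

#' Write a study bundle to a directory
#'
#' Serializes every artifact of a [simulate_study()] bundle as plain text
#' (sequences as JSON, tables as CSV) together with a manifest recording the
#' seed, the configuration and the file list, so that the bundle can be
#' re-generated or re-read exactly.
#'
#' @param bundle a \code{study_bundle}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_sequences(bundle$sequences, fp("sequences.json"))
  write_table_csv(bundle$schedules, fp("schedules.csv"))
  write_answers_csv(bundle$answers, fp("answers.csv"))
  write_table_csv(bundle$pretest, fp("pretest.csv"))
  write_table_csv(bundle$participants, fp("participants.csv"))
  cfg <- bundle$config
  cfg$design <- unclass(cfg$design)
  manifest <- list(
    package = "avspan",
    version = as.character(utils::packageVersion("avspan")),
    seed = bundle$seed,
    config = unclass(cfg),
    files = c("sequences.json", "schedules.csv", "answers.csv",
              "pretest.csv", "participants.csv"))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  manifest <- jsonlite::read_json(fp("manifest.json"), simplifyVector = TRUE)
  for (f in manifest$files) {
    if (!file.exists(fp(f))) stop("bundle file missing: ", f)
  }
  cfg <- manifest$config
  design <- do.call(design_config, cfg$design[setdiff(names(cfg$design),
                                                      "blacklist")])
  cfg$design <- NULL
  config <- do.call(sim_config, c(cfg, list(design = design)))
  structure(list(
    sequences = read_sequences(fp("sequences.json")),
    participants = read_table_csv(fp("participants.csv")),
    schedules = read_table_csv(fp("schedules.csv")),
    answers = read_answers_csv(fp("answers.csv")),
    pretest = read_table_csv(fp("pretest.csv")),
    config = config,
    seed = manifest$seed), class = "study_bundle")
}
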