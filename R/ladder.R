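#' Staged multilevel model ladder for an ordinal outcome score
#'
#' Automates the step-wise construction of a cumulative-link mixed model,
#' mirroring the X0-X5 build-up used for the digit-span outcome scores:
#' \describe{
#'   \item{X0}{random participant intercept plus trial order:
#'     \code{~ Order + (1 | Participant)}.}
#'   \item{X1}{adds the experimental variables \code{Sequence} and
#'     \code{Condition}.}
#'   \item{X2}{adds person-level covariates one at a time, retaining those
#'     whose likelihood-ratio test against the current model has
#'     p < \code{alpha}.}
#'   \item{X3}{adds \code{Condition:covariate} interactions (optionally
#'     \code{Sequence:covariate}) retained the same way.}
#'   \item{X4}{upgrades the random structure to a correlated random order
#'     slope \code{(1 + Order | Participant)}, adds
#'     \code{Order:covariate} terms retained by LR test, and checks
#'     \code{Order^2} and \code{Order:Condition}, dropping them when they do
#'     not improve the model.}
#'   \item{X5}{backward simplification: repeatedly removes the term whose
#'     removal is least harmful as long as the removal is not significant
#'     at \code{alpha}.}
#' }
#' A stage that fails to converge is flagged and the ladder continues from
#' the last converged stage.
#'
#' @param data scored dataset, one row per trial, with columns for the
#'   response, \code{Participant}, \code{Order}, \code{Condition},
#'   \code{Sequence} and all covariates.
#' @param response name of the ordinal response column (factor or ordered).
#' @param covariates character vector of person-level covariate columns.
#' @param alpha retention threshold for LR tests (default 0.05).
#' @param include_sequence_interactions also try Sequence:covariate terms
#'   at X3 (off by default; expensive with 30 sequence levels).
#' @param participant,order,condition,sequence column names.
#' @param control passed to [cumlink()].
#' @return object of class \code{cumlink_ladder}: list of stages, each with
#'   \code{name}, \code{formula}, \code{fit}, \code{p_vs_previous}.
#' @export
run_ladder <- function(data, response, covariates = character(0),
                       alpha = 0.05, include_sequence_interactions = FALSE,
                       participant = "Participant", order = "Order",
                       condition = "Condition", sequence = "Sequence",
                       control = cumlink_control()) {
  data[[participant]] <- factor(data[[participant]])
  data[[condition]] <- factor(data[[condition]])
  data[[sequence]] <- factor(data[[sequence]])

  fit_formula <- function(rhs) {
    fml <- stats::as.formula(paste(response, "~", rhs))
    tryCatch(cumlink(fml, data, control = control),
             error = function(e) structure(list(error = conditionMessage(e),
                                                converged = FALSE),
                                           class = "cumlink_failed"))
  }
  ok <- function(f) inherits(f, "cumlink") && isTRUE(f$converged)

  stages <- list()
  push <- function(name, rhs, fit, p) {
    stages[[length(stages) + 1L]] <<- list(
      name = name, formula = paste("~", rhs), fit = fit, p_vs_previous = p)
  }

  re1 <- sprintf("(1 | %s)", participant)
  re2 <- sprintf("(1 + %s | %s)", order, participant)

  # X0
  rhs0 <- paste(order, "+", re1)
  f0 <- fit_formula(rhs0)
  push("X0", rhs0, f0, NA_real_)
  if (!ok(f0)) return(finish_ladder(stages))
  cur_rhs <- rhs0
  cur_fit <- f0

  # X1: experimental variables
  rhs1 <- paste(order, "+", sequence, "+", condition, "+", re1)
  f1 <- fit_formula(rhs1)
  p1 <- if (ok(f1)) lr_test(cur_fit, f1)$p else NA_real_
  push("X1", rhs1, f1, p1)
  if (ok(f1)) { cur_rhs <- rhs1; cur_fit <- f1 }

  add_retained <- function(base_rhs, base_fit, candidates) {
    kept <- character(0)
    rhs <- base_rhs
    fit <- base_fit
    for (term in candidates) {
      rhs_try <- paste(rhs, "+", term)
      f_try <- fit_formula(rhs_try)
      if (!ok(f_try)) next
      p <- tryCatch(lr_test(fit, f_try)$p, error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) {
        kept <- c(kept, term)
        rhs <- rhs_try
        fit <- f_try
      }
    }
    list(rhs = rhs, fit = fit, kept = kept)
  }

  # X2: person-level main effects
  s2 <- add_retained(cur_rhs, cur_fit, covariates)
  p2 <- if (length(s2$kept)) lr_test(cur_fit, s2$fit)$p else NA_real_
  push("X2", s2$rhs, s2$fit, p2)
  cur_rhs <- s2$rhs; cur_fit <- s2$fit

  # X3: condition (and optionally sequence) interactions
  cands3 <- paste0(condition, ":", covariates)
  if (include_sequence_interactions)
    cands3 <- c(cands3, paste0(sequence, ":", covariates))
  s3 <- add_retained(cur_rhs, cur_fit, cands3)
  p3 <- if (length(s3$kept)) lr_test(cur_fit, s3$fit)$p else NA_real_
  push("X3", s3$rhs, s3$fit, p3)
  cur_rhs <- s3$rhs; cur_fit <- s3$fit

  # X4: random order slope + Order interactions; probe Order^2, Order:Condition
  rhs4 <- sub(re1, re2, cur_rhs, fixed = TRUE)
  f4 <- fit_formula(rhs4)
  if (ok(f4)) {
    s4 <- add_retained(rhs4, f4, paste0(order, ":", covariates))
    rhs4 <- s4$rhs; f4 <- s4$fit
    for (probe in c(sprintf("I(%s^2)", order),
                    paste0(order, ":", condition))) {
      rhs_try <- paste(rhs4, "+", probe)
      f_try <- fit_formula(rhs_try)
      if (ok(f_try)) {
        p <- tryCatch(lr_test(f4, f_try)$p, error = function(e) NA_real_)
        if (!is.na(p) && p < alpha) { rhs4 <- rhs_try; f4 <- f_try }
      }
    }
    p4 <- lr_test(cur_fit, f4)$p
    push("X4", rhs4, f4, p4)
    cur_rhs <- rhs4; cur_fit <- f4
  } else {
    push("X4", rhs4, f4, NA_real_)
  }

  # X5: backward simplification
  repeat {
    terms_now <- attr(stats::terms(stats::as.formula(paste("y ~",
      gsub("\\(1( \\+ [^|]*)? \\| [^)]*\\)", "1", cur_rhs)))), "term.labels")
    droppable <- setdiff(terms_now, c(order, sequence, condition))
    droppable <- c(droppable, intersect(terms_now, c(sequence, condition)))
    best <- NULL
    for (term in droppable) {
      # only drop mains not involved in retained interactions
      if (term %in% c(sequence, condition) &&
          any(grepl(paste0(term, ":"), terms_now, fixed = TRUE))) next
      rhs_try <- drop_term(cur_rhs, term)
      f_try <- fit_formula(rhs_try)
      if (!ok(f_try)) next
      p <- tryCatch(lr_test(f_try, cur_fit)$p, error = function(e) NA_real_)
      if (!is.na(p) && p >= alpha && (is.null(best) || p > best$p))
        best <- list(rhs = rhs_try, fit = f_try, p = p)
    }
    if (is.null(best)) break
    cur_rhs <- best$rhs
    cur_fit <- best$fit
  }
  p5 <- tryCatch(lr_test(cur_fit, stages[[length(stages)]]$fit)$p,
                 error = function(e) NA_real_)
  push("X5", cur_rhs, cur_fit, p5)
  finish_ladder(stages)
}

drop_term <- function(rhs, term) {
  parts <- strsplit(rhs, " + ", fixed = TRUE)[[1]]
  paste(parts[parts != term], collapse = " + ")
}

finish_ladder <- function(stages) {
  structure(list(stages = stages), class = "cumlink_ladder")
}

#' @export
print.cumlink_ladder <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Cumulative-link model ladder\n")
  print(df, right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cumlink_ladder <- function(x, ...) {
  rows <- lapply(x$stages, function(s) {
    failed <- !inherits(s$fit, "cumlink")
    data.frame(
      name = s$name,
      formula = s$formula,
      converged = if (failed) FALSE else s$fit$converged,
      n_params = if (failed) NA_real_ else s$fit$n_params,
      logLik = if (failed) NA_real_ else s$fit$logLik,
      AIC = if (failed) NA_real_ else s$fit$aic,
      p_vs_previous = s$p_vs_previous,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ordinal response binning for the outcome scores
#'
#' Converts a numeric score into an ordered factor. \code{"observed"} uses
#' each distinct observed value as a category. \code{"binned"} applies a
#' fixed-width scheme: per-digit accuracy rounded to the nearest fifth
#' (six categories 0, 0.2, ..., 1), distraction in 0.2-wide bins on
#' \code{[-1, 1]}; Levenshtein distances are already integer-valued and use
#' observed categories in both schemes.
#'
#' @param x numeric score vector.
#' @param score one of \code{"per_digit"}, \code{"levenshtein"},
#'   \code{"distraction"}.
#' @param scheme \code{"observed"} or \code{"binned"}.
#' @return an ordered factor.
#' @export
ordinal_response <- function(x, score = c("per_digit", "levenshtein",
                                          "distraction"),
                             scheme = c("observed", "binned")) {
  score <- match.arg(score)
  scheme <- match.arg(scheme)
  if (scheme == "observed" || score == "levenshtein")
    return(factor(x, levels = sort(unique(x)), ordered = TRUE))
  if (score == "per_digit") {
    b <- round(x * 5) / 5
    return(factor(b, levels = sort(unique(b)), ordered = TRUE))
  }
  b <- floor(clamp(x, -1, 1 - 1e-9) / 0.2) * 0.2 + 0.1   # bin midpoints
  factor(round(b, 10), levels = sort(unique(round(b, 10))), ordered = TRUE)
}
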