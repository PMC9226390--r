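#' @export
print.cumlink <- function(x, ...) {
  cat("Cumulative link", if (!is.null(x$re_covariance)) "mixed", "model (logit)\n")
  cat("formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("logLik %.2f  AIC %.2f  n %d  params %d  %s\n",
              x$logLik, x$aic, x$nobs, x$n_params,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (length(x$beta)) {
    cat("\nCoefficients:\n")
    print(round(x$beta, 5))
  }
  if (!is.null(x$re_sd)) {
    cat("\nRandom effects (", x$group_name, ") std.dev.: ",
        paste(sprintf("%s %.4f", names(x$re_sd), x$re_sd), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cumlink <- function(object, ...) {
  cf <- c(object$alpha, object$beta)
  se <- sqrt(diag(object$vcov))
  z <- cf / se
  tab <- cbind(Estimate = cf, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab,
              n_thresholds = length(object$alpha))
  class(out) <- "summary.cumlink"
  out
}

#' @export
print.summary.cumlink <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table (thresholds first):\n")
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.cumlink <- function(object, ...) object$coefficients

#' @export
vcov.cumlink <- function(object, ...) object$vcov

#' @export
logLik.cumlink <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.cumlink <- function(object, ...) object$nobs

#' Predicted category probabilities
#'
#' Probabilities are conditional on random effects equal to zero (the
#' population-median participant).
#'
#' @param object a [cumlink()] fit.
#' @param newdata data.frame of covariates; the fitted frame is reused when
#'   omitted is not supported (supply newdata).
#' @param type \code{"prob"} for the K-column probability matrix,
#'   \code{"class"} for the modal category label.
#' @param ... unused.
#' @export
predict.cumlink <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  eta <- if (length(object$beta)) drop(X[, names(object$beta), drop = FALSE] %*% object$beta)
         else rep(0, nrow(mf))
  K <- object$K
  cum <- vapply(object$alpha, function(th) stats::plogis(th - eta),
                numeric(length(eta)))
  cum <- cbind(matrix(cum, ncol = K - 1L), 1)
  pr <- cbind(cum[, 1L], t(apply(cum, 1, diff)))
  if (K == 2L) pr <- cbind(cum[, 1L], 1 - cum[, 1L])
  colnames(pr) <- object$y_levels
  if (type == "class") return(object$y_levels[max.col(pr)])
  pr
}

#' Simulate ordinal responses from a fitted model
#'
#' Draws new responses at the fitted parameters, with fresh random effects
#' sampled from the estimated covariance (mixed fits) for the grouping
#' structure in \code{newdata}.
#'
#' @param object a [cumlink()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param newdata data.frame of covariates (and the grouping column for
#'   mixed fits).
#' @param ... unused.
#' @return data.frame of \code{nsim} factor columns.
#' @export
simulate.cumlink <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  with_seed(seed, {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
    eta_fix <- if (length(object$beta))
      drop(X[, names(object$beta), drop = FALSE] %*% object$beta)
      else rep(0, nrow(mf))
    out <- vector("list", nsim)
    for (s in seq_len(nsim)) {
      eta <- eta_fix
      if (!is.null(object$re_covariance)) {
        grp <- factor(newdata[[object$group_name]])
        L <- t(chol(object$re_covariance + diag(1e-12, nrow(object$re_covariance))))
        u <- t(L %*% matrix(stats::rnorm(nlevels(grp) * nrow(L)), nrow(L)))
        eta <- eta + u[as.integer(grp), 1L]
        if (!is.null(object$re_slope))
          eta <- eta + u[as.integer(grp), 2L] * newdata[[object$re_slope]]
      }
      cum <- vapply(object$alpha, function(th) stats::plogis(th - eta),
                    numeric(length(eta)))
      cum <- cbind(matrix(cum, ncol = object$K - 1L), 1)
      r <- stats::runif(nrow(cum))
      yi <- rowSums(sweep(cum, 1, r, "<")) + 1L
      out[[s]] <- factor(object$y_levels[yi], levels = object$y_levels)
    }
    names(out) <- paste0("sim_", seq_len(nsim))
    as.data.frame(out)
  })
}

#' Likelihood-ratio test of two nested fits
#'
#' Chi-squared test on twice the log-likelihood difference with degrees of
#' freedom equal to the parameter-count difference.
#'
#' @param fit_small,fit_big nested [cumlink()] fits; \code{fit_big} must
#'   have strictly more parameters (equal-parameter identical fits are
#'   allowed and give p = 1).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
lr_test <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "cumlink"), inherits(fit_big, "cumlink"))
  df <- fit_big$n_params - fit_small$n_params
  if (df < 0L) stop("fit_big must have at least as many parameters as fit_small")
  strip_bars <- function(f) {
    tl <- attr(stats::terms(f), "term.labels")
    tl[!grepl("|", tl, fixed = TRUE)]
  }
  small_terms <- strip_bars(fit_small$formula)
  big_terms <- strip_bars(fit_big$formula)
  if (!all(small_terms %in% big_terms))
    stop("models do not appear nested: ",
         paste(setdiff(small_terms, big_terms), collapse = ", "),
         " not in the larger model")
  stat <- max(0, 2 * (fit_big$logLik - fit_small$logLik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' @export
anova.cumlink <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- fits[vapply(fits, inherits, logical(1), "cumlink")]
  if (length(fits) < 2L) stop("supply at least two cumlink fits")
  fits <- fits[order(vapply(fits, function(f) f$n_params, numeric(1)))]
  out <- data.frame(
    formula = vapply(fits, function(f) deparse1(f$formula), character(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AIC = vapply(fits, function(f) f$aic, numeric(1)),
    statistic = NA_real_, df = NA_real_, p = NA_real_)
  for (i in 2:length(fits)) {
    lt <- lr_test(fits[[i - 1L]], fits[[i]])
    out$statistic[i] <- lt$statistic
    out$df[i] <- lt$df
    out$p[i] <- lt$p
  }
  out
}

#' Odds ratios from coefficients
#'
#' For a model coefficient \eqn{b} (log-odds per unit), the odds ratio over
#' \code{k_units} is \eqn{\exp(b)^{k}}. For interaction settings supply
#' \code{at}: a named vector of variable values; the composed odds ratio is
#' the product over all named coefficients of \eqn{\exp(b_t)^{v_t}}, i.e.
#' main effects and interaction terms each raised to their variable values.
#'
#' @param object a [cumlink()] fit, or a bare numeric coefficient
#'   (log-odds scale).
#' @param term coefficient name (fit method) — ignored when \code{at} given.
#' @param k_units number of units of change (default 1).
#' @param at named numeric vector of coefficient multipliers for composed
#'   (interaction) settings.
#' @param ... unused.
#' @return a single odds ratio.
#' @examples
#' odds_ratio(log(0.75428), k_units = 5)  # 0.24415
#' @export
odds_ratio <- function(object, ...) UseMethod("odds_ratio")

#' @rdname odds_ratio
#' @export
odds_ratio.numeric <- function(object, k_units = 1, ...) {
  stopifnot(length(object) == 1L)
  exp(object)^k_units
}

#' @rdname odds_ratio
#' @export
odds_ratio.cumlink <- function(object, term = NULL, k_units = 1, at = NULL, ...) {
  if (!is.null(at)) {
    miss <- setdiff(names(at), names(object$beta))
    if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
    return(prod(exp(object$beta[names(at)])^at))
  }
  if (is.null(term) || !term %in% names(object$beta))
    stop("unknown term: ", term %||% "<missing>")
  exp(object$beta[[term]])^k_units
}
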