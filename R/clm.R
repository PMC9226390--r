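#' Cumulative-link (mixed) ordinal regression
#'
#' Fits a proportional-odds model for an ordinal response,
#' \deqn{P(Y_i \le k) = \mathrm{logistic}(\theta_k - x_i'\beta - z_i'u_{j(i)}),}
#' with strictly increasing thresholds \eqn{\theta_1 < \dots < \theta_{K-1}}
#' and, optionally, participant-level random effects written in the formula
#' as \code{(1 | group)} or \code{(1 + slope | group)} (random intercept, or
#' correlated random intercept and slope). Fixed-effects models are fitted by
#' BFGS on the exact log-likelihood with analytic gradient; thresholds are
#' kept monotone through a log-increment parameterization. Mixed models
#' maximize the marginal likelihood, integrating the random effects by a
#' Laplace approximation (per-group inner Newton for the conditional mode
#' plus a log-determinant correction) or, for random-intercept models, by
#' adaptive Gauss-Hermite quadrature.
#'
#' @param formula model formula; the response must be a factor, ordered
#'   factor, or something coercible to one. At most one random-effect term
#'   of the form \code{(1 | g)} or \code{(1 + v | g)} is supported.
#' @param data data.frame containing all variables.
#' @param method \code{"laplace"} (default) or \code{"agq"} (adaptive
#'   Gauss-Hermite; random-intercept models only).
#' @param nagq number of quadrature nodes when \code{method = "agq"}.
#' @param start optional named start values (internal parameterization).
#' @param control list of optimizer settings, see [cumlink_control()].
#' @return an object of class \code{cumlink} with components including
#'   \code{alpha} (thresholds), \code{beta} (fixed effects),
#'   \code{re_covariance} and \code{re_sd} (random-effect covariance and
#'   standard deviations, if any), \code{logLik}, \code{aic},
#'   \code{n_params}, \code{vcov}, \code{converged} and \code{ranef}
#'   (conditional modes).
#' @seealso [odds_ratio()], [lr_test()], [run_ladder()]
#' @examples
#' d <- data.frame(y = factor(rep(1:3, each = 20)),
#'                 x = rnorm(60) + rep(0:2, each = 20))
#' f <- cumlink(y ~ x, d)
#' coef(f); AIC(f)
#' @export
cumlink <- function(formula, data, method = c("laplace", "agq"), nagq = 7L,
                    start = NULL, control = cumlink_control()) {
  method <- match.arg(method)
  cl <- match.call()
  pf <- parse_re_formula(formula)
  mf <- stats::model.frame(pf$fixed, data, na.action = stats::na.fail)
  y_raw <- stats::model.response(mf)
  if (!is.factor(y_raw)) y_raw <- factor(y_raw)
  y <- as.integer(droplevels(y_raw))
  K <- max(y)
  if (K < 2L) stop("response needs at least 2 observed categories")
  mt <- attr(mf, "terms")
  X_full <- stats::model.matrix(mt, mf)
  int_col <- which(colnames(X_full) == "(Intercept)")
  X <- if (length(int_col)) X_full[, -int_col, drop = FALSE] else X_full
  p <- ncol(X)

  re <- NULL
  if (!is.null(pf$re)) {
    grp_f <- factor(data[[pf$re$group]])
    slope <- NULL
    if (!is.null(pf$re$slope)) {
      slope <- data[[pf$re$slope]]
      if (!is.numeric(slope)) stop("random slope variable must be numeric")
    }
    re <- list(group = grp_f, g = as.integer(grp_f), J = nlevels(grp_f),
               slope = slope, slope_name = pf$re$slope,
               group_name = pf$re$group)
  }

  fit <- cumlink_engine(y, K, X, re, method, nagq, start, control)
  fit$call <- cl
  fit$formula <- formula
  fit$terms <- mt
  fit$xlevels <- stats::.getXlevels(mt, mf)
  fit$y_levels <- levels(droplevels(y_raw))
  fit$nobs <- length(y)
  class(fit) <- "cumlink"
  fit
}

#' Optimizer settings for [cumlink()]
#'
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param inner_tol gradient tolerance of the per-group Newton solver for
#'   the conditional random-effect modes.
#' @param max_iter maximum outer iterations.
#' @param inner_max_iter maximum inner Newton iterations.
#' @return a list of settings.
#' @export
cumlink_control <- function(rel_tol = 1e-8, inner_tol = 1e-10,
                            max_iter = 200L, inner_max_iter = 60L) {
  list(rel_tol = rel_tol, inner_tol = inner_tol, max_iter = max_iter,
       inner_max_iter = inner_max_iter)
}

# ---- formula parsing: split lme4-style random-effect bars --------------

parse_re_formula <- function(formula) {
  rhs <- formula[[3]]
  bars <- list()
  strip <- function(e) {
    if (is.call(e) && identical(e[[1]], as.name("("))) {
      inner <- e[[2]]
      if (is.call(inner) && identical(inner[[1]], as.name("|"))) {
        bars[[length(bars) + 1L]] <<- inner
        return(NULL)
      }
      return(e)
    }
    if (is.call(e) && identical(e[[1]], as.name("+"))) {
      a <- strip(e[[2]])
      b <- strip(e[[3]])
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      return(call("+", a, b))
    }
    e
  }
  fixed_rhs <- strip(rhs)
  if (is.null(fixed_rhs)) fixed_rhs <- 1
  fixed <- formula
  fixed[[3]] <- fixed_rhs
  if (!length(bars)) return(list(fixed = fixed, re = NULL))
  if (length(bars) > 1L) stop("at most one random-effect term is supported")
  bar <- bars[[1]]
  group <- deparse(bar[[3]])
  lhs <- bar[[2]]
  terms_chr <- attr(stats::terms(stats::reformulate(deparse(lhs))), "term.labels")
  has_int <- attr(stats::terms(stats::reformulate(deparse(lhs))), "intercept") == 1
  if (!has_int) stop("random-effect term must include an intercept")
  if (length(terms_chr) > 1L) stop("at most one random slope is supported")
  slope <- if (length(terms_chr)) terms_chr else NULL
  list(fixed = fixed, re = list(group = group, slope = slope))
}

# ---- likelihood pieces -------------------------------------------------

# per-observation log-likelihood and derivatives in the linear predictor.
# eta is x'beta + random part; cell probability P = F(th[y]-eta) - F(th[y-1]-eta)
ord_ll_parts <- function(y, K, eta, theta, deriv = 2L) {
  up <- c(theta, Inf)[y] - eta
  lo <- c(-Inf, theta)[y] - eta
  Fu <- stats::plogis(up)
  Fl <- stats::plogis(lo)
  P <- pmax(Fu - Fl, 1e-300)
  out <- list(ll = log(P), P = P)
  if (deriv >= 1L) {
    fu <- stats::dlogis(up)
    fl <- stats::dlogis(lo)
    out$d1 <- -(fu - fl) / P              # d ll / d eta
    if (deriv >= 2L) {
      dfu <- fu * (1 - 2 * Fu)            # f'(up)
      dfl <- fl * (1 - 2 * Fl)
      out$d2 <- (dfu - dfl) / P - out$d1^2   # d2 ll / d eta2 (<= 0)
      out$fu <- fu; out$fl <- fl
    }
  }
  out
}

theta_from_par <- function(tpar, K) {
  if (K == 2L) return(tpar[1])
  cumsum(c(tpar[1], exp(tpar[2:(K - 1L)])))
}

# start values: empirical cumulative logits, beta = 0
cumlink_start <- function(y, K, p, n_lambda) {
  cum <- cumsum(tabulate(y, K))[1:(K - 1L)] / length(y)
  cum <- clamp(cum, 1e-3, 1 - 1e-3)
  th <- stats::qlogis(cum)
  th <- cummax(th + seq_len(K - 1L) * 1e-8)   # enforce strict increase
  tpar <- c(th[1], if (K > 2L) log(pmax(diff(th), 1e-4)))
  lam0 <- if (n_lambda == 0L) numeric(0) else if (n_lambda == 1L) 0.5
          else c(0.5, 0, 0.3)
  c(tpar, rep(0, p), lam0)
}

# ---- engine ------------------------------------------------------------

cumlink_engine <- function(y, K, X, re, method, nagq, start, control) {
  n <- length(y)
  p <- ncol(X)
  # standardize X columns for optimizer conditioning; back-transform after
  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")

  q <- 0L
  z_scale <- 1
  if (!is.null(re)) {
    q <- if (is.null(re$slope)) 1L else 2L
    if (q == 2L) {
      z_scale <- stats::sd(re$slope)
      if (z_scale < 1e-12) z_scale <- 1
      re$zs <- re$slope / z_scale
    }
  }
  n_lambda <- if (q == 0L) 0L else q * (q + 1L) / 2L
  n_tpar <- K - 1L

  idx_t <- seq_len(n_tpar)
  idx_b <- if (p) n_tpar + seq_len(p) else integer(0)
  idx_l <- if (n_lambda) n_tpar + p + seq_len(n_lambda) else integer(0)

  if (q > 0L) {
    vhat <- matrix(0, re$J, q)   # warm-started conditional modes (scaled)
    g <- re$g
  }

  # inner Newton: maximize sum_i ll_i(eta_fix + (Z Lam v)_i) - |v|^2/2
  inner_modes <- function(eta_fix, theta, Lam) {
    for (it in seq_len(control$inner_max_iter)) {
      u1 <- Lam[1, 1] * vhat[g, 1]
      if (q == 2L) u1 <- u1 + (Lam[2, 1] * vhat[g, 1] + Lam[2, 2] * vhat[g, 2]) * re$zs
      parts <- ord_ll_parts(y, K, eta_fix + u1, theta, deriv = 2L)
      w <- -parts$d2
      if (q == 1L) {
        gr <- Lam[1, 1] * rowsum_vec(parts$d1, g, re$J) - vhat[, 1]
        h <- Lam[1, 1]^2 * rowsum_vec(w, g, re$J) + 1
        step <- clamp(gr / h, -3, 3)   # damp early overshoot
        vhat[, 1] <<- vhat[, 1] + step
        if (max(abs(gr)) < control$inner_tol) break
      } else {
        # per-group gradient/Hessian of h(v); rows of Z Lam are
        # (Lam11, Lam21*z + 0) ... derive via chain: d eta/d v1 = Lam11 + Lam21*z,
        # d eta/d v2 = Lam22*z
        a1 <- Lam[1, 1] + Lam[2, 1] * re$zs
        a2 <- Lam[2, 2] * re$zs
        g1 <- rowsum_vec(parts$d1 * a1, g, re$J) - vhat[, 1]
        g2 <- rowsum_vec(parts$d1 * a2, g, re$J) - vhat[, 2]
        h11 <- rowsum_vec(w * a1 * a1, g, re$J) + 1
        h12 <- rowsum_vec(w * a1 * a2, g, re$J)
        h22 <- rowsum_vec(w * a2 * a2, g, re$J) + 1
        det <- h11 * h22 - h12^2
        s1 <- clamp((h22 * g1 - h12 * g2) / det, -3, 3)
        s2 <- clamp((h11 * g2 - h12 * g1) / det, -3, 3)
        vhat[, 1] <<- vhat[, 1] + s1
        vhat[, 2] <<- vhat[, 2] + s2
        if (max(abs(c(g1, g2))) < control$inner_tol) break
      }
    }
    invisible(NULL)
  }

  laplace_nll <- function(par) {
    theta <- theta_from_par(par[idx_t], K)
    eta_fix <- if (p) drop(Xs %*% par[idx_b]) else rep(0, n)
    Lam <- lambda_matrix(par[idx_l], q)
    inner_modes(eta_fix, theta, Lam)
    u1 <- Lam[1, 1] * vhat[g, 1]
    if (q == 2L) u1 <- u1 + (Lam[2, 1] * vhat[g, 1] + Lam[2, 2] * vhat[g, 2]) * re$zs
    parts <- ord_ll_parts(y, K, eta_fix + u1, theta, deriv = 2L)
    w <- -parts$d2
    ll_data <- rowsum_vec(parts$ll, g, re$J)
    pen <- 0.5 * rowSums(vhat^2)
    if (q == 1L) {
      h <- Lam[1, 1]^2 * rowsum_vec(w, g, re$J) + 1
      logdet <- log(h)
    } else {
      a1 <- Lam[1, 1] + Lam[2, 1] * re$zs
      a2 <- Lam[2, 2] * re$zs
      h11 <- rowsum_vec(w * a1 * a1, g, re$J) + 1
      h12 <- rowsum_vec(w * a1 * a2, g, re$J)
      h22 <- rowsum_vec(w * a2 * a2, g, re$J) + 1
      logdet <- log(pmax(h11 * h22 - h12^2, 1e-300))
    }
    -sum(ll_data - pen - 0.5 * logdet)
  }

  agq_nll <- function(par) {
    if (q != 1L) stop("adaptive quadrature is available for random-intercept models only")
    theta <- theta_from_par(par[idx_t], K)
    eta_fix <- if (p) drop(Xs %*% par[idx_b]) else rep(0, n)
    Lam <- lambda_matrix(par[idx_l], q)
    inner_modes(eta_fix, theta, Lam)
    parts <- ord_ll_parts(y, K, eta_fix + Lam[1, 1] * vhat[g, 1], theta, deriv = 2L)
    hcur <- Lam[1, 1]^2 * rowsum_vec(-parts$d2, g, re$J) + 1
    sig <- 1 / sqrt(hcur)
    gh <- gauss_hermite(nagq)
    # log L_j = log sum_k w_k exp(x_k^2) * sqrt(2)*sig_j/sqrt(2*pi) * exp(h_j(v_jk))
    hmat <- matrix(0, re$J, nagq)
    for (k in seq_len(nagq)) {
      vk <- vhat[, 1] + sqrt(2) * sig * gh$nodes[k]
      pk <- ord_ll_parts(y, K, eta_fix + Lam[1, 1] * vk[g], theta, deriv = 0L)
      hmat[, k] <- rowsum_vec(pk$ll, g, re$J) - 0.5 * vk^2
    }
    hmax <- apply(hmat, 1, max)
    lw <- log(gh$weights) + gh$nodes^2
    s <- rowSums(exp(sweep(hmat, 1, hmax) + rep(lw, each = re$J)))
    llj <- hmax + log(s) + 0.5 * log(2) + log(sig) - 0.5 * log(2 * pi)
    -sum(llj)
  }

  clm_nll <- function(par) {
    theta <- theta_from_par(par[idx_t], K)
    eta <- if (p) drop(Xs %*% par[idx_b]) else rep(0, n)
    -sum(ord_ll_parts(y, K, eta, theta, deriv = 0L)$ll)
  }

  clm_grad <- function(par) {
    theta <- theta_from_par(par[idx_t], K)
    eta <- if (p) drop(Xs %*% par[idx_b]) else rep(0, n)
    parts <- ord_ll_parts(y, K, eta, theta, deriv = 2L)
    # d ll_i / d theta_k = [f(up) 1(y=k) - f(lo) 1(y-1=k)] / P
    gth <- numeric(K - 1L)
    ru <- parts$fu / parts$P
    rl <- parts$fl / parts$P
    for (k in seq_len(K - 1L)) {
      gth[k] <- sum(ru[y == k]) - sum(rl[y == k + 1L])
    }
    # chain to (t1, log-increments)
    gt <- numeric(K - 1L)
    gt[1] <- sum(gth)
    if (K > 2L) {
      for (j in 2:(K - 1L)) gt[j] <- exp(par[idx_t][j]) * sum(gth[j:(K - 1L)])
    }
    gb <- if (p) drop(crossprod(Xs, parts$d1)) else numeric(0)
    -c(gt, gb)
  }

  par0 <- start %||% cumlink_start(y, K, p, n_lambda)

  if (q == 0L) {
    opt <- stats::optim(par0, clm_nll, clm_grad, method = "BFGS",
                        control = list(maxit = control$max_iter,
                                       reltol = control$rel_tol))
    par_hat <- opt$par
    # Newton polish to drive the gradient below tolerance
    for (it in 1:20) {
      gr <- clm_grad(par_hat)
      if (max(abs(gr)) < 1e-8) break
      Hn <- fd_hessian(clm_nll, par_hat)
      step <- tryCatch(solve(Hn, gr), error = function(e) NULL)
      if (is.null(step)) break
      cand <- par_hat - step
      if (clm_nll(cand) <= clm_nll(par_hat) + 1e-9) par_hat <- cand else break
    }
    converged <- opt$convergence == 0L || max(abs(clm_grad(par_hat))) < 1e-6
    nll <- clm_nll(par_hat)
    message <- if (converged) "converged" else paste("optim code", opt$convergence)
  } else {
    obj <- if (method == "laplace") laplace_nll else agq_nll
    lower <- rep(-Inf, length(par0))
    diag_idx <- if (q == 1L) 1L else c(1L, 3L)   # (l11) or (l11, l21, l22)
    lower[idx_l[diag_idx]] <- 0
    opt <- stats::nlminb(par0, obj, lower = lower,
                         control = list(iter.max = control$max_iter,
                                        eval.max = 4L * control$max_iter,
                                        rel.tol = control$rel_tol))
    converged <- opt$convergence == 0L
    par_hat <- opt$par
    nll <- opt$objective
    message <- opt$message
  }

  theta_s <- theta_from_par(par_hat[idx_t], K)
  beta_s <- par_hat[idx_b]

  # back-transform standardized coefficients
  beta <- if (p) beta_s / xs else numeric(0)
  shift <- if (p) sum(beta * xc) else 0
  theta <- theta_s + shift

  # delta-method vcov on the original (theta, beta) scale
  H <- fd_hessian(if (q == 0L) clm_nll else if (method == "laplace") laplace_nll
                  else agq_nll, par_hat)
  vc <- tryCatch(solve(H), error = function(e) {
    blk <- c(idx_t, idx_b)
    out <- matrix(NA_real_, length(par_hat), length(par_hat))
    out[blk, blk] <- tryCatch(solve(H[blk, blk]), error = function(e2)
      matrix(NA_real_, length(blk), length(blk)))
    out
  })
  Jac <- param_jacobian(par_hat, K, p, xc, xs, idx_t, idx_b)
  vcov_tb <- Jac %*% vc[c(idx_t, idx_b), c(idx_t, idx_b), drop = FALSE] %*% t(Jac)

  re_cov <- re_sd <- ranef <- NULL
  lambda <- NULL
  if (q > 0L) {
    Lam <- lambda_matrix(par_hat[idx_l], q)
    # undo random-slope scaling: u_orig = D Lam v with D = diag(1, 1/z_scale)
    D <- diag(c(1, 1 / z_scale)[seq_len(q)], q)
    L0 <- D %*% Lam
    re_cov <- L0 %*% t(L0)
    nm <- c("(Intercept)", re$slope_name)[seq_len(q)]
    dimnames(re_cov) <- list(nm, nm)
    re_sd <- sqrt(diag(re_cov))
    ranef <- vhat %*% t(L0)
    colnames(ranef) <- nm
    rownames(ranef) <- levels(re$group)
    lambda <- par_hat[idx_l]
  }

  tn <- paste(seq_len(K - 1L), seq(2L, K), sep = "|")
  names(theta) <- tn
  if (p) names(beta) <- colnames(X)
  dimnames(vcov_tb) <- list(c(tn, names(beta)), c(tn, names(beta)))

  n_params <- length(par_hat)
  ll <- -nll
  list(alpha = theta, beta = beta, coefficients = c(theta, beta),
       re_covariance = re_cov, re_sd = re_sd, ranef = ranef,
       logLik = ll, n_params = n_params, aic = -2 * ll + 2 * n_params,
       vcov = vcov_tb, converged = converged, message = message,
       method = if (q == 0L) "ml" else method, nagq = if (q == 1L) nagq else NA,
       K = K, n_fixed = p, group_name = if (q > 0L) re$group_name else NULL,
       re_slope = if (q > 0L) re$slope_name else NULL,
       par = par_hat, lambda = lambda, z_scale = z_scale,
       x_center = xc, x_scale = xs)
}

lambda_matrix <- function(lpar, q) {
  if (q == 1L) return(matrix(lpar[1], 1, 1))
  matrix(c(lpar[1], lpar[2], 0, lpar[3]), 2, 2, byrow = FALSE)[, , drop = FALSE]
}

rowsum_vec <- function(x, g, J) {
  out <- numeric(J)
  tmp <- rowsum(x, g)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

# central-difference Hessian of scalar function f at x
fd_hessian <- function(f, x, h = 1e-4) {
  m <- length(x)
  H <- matrix(0, m, m)
  hv <- pmax(h, h * abs(x))
  f0 <- f(x)
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + hv[i]
        xm <- x; xm[i] <- x[i] - hv[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hv[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + hv[i]; xpp[j] <- x[j] + hv[j]
        xpm <- x; xpm[i] <- x[i] + hv[i]; xpm[j] <- x[j] - hv[j]
        xmp <- x; xmp[i] <- x[i] - hv[i]; xmp[j] <- x[j] + hv[j]
        xmm <- x; xmm[i] <- x[i] - hv[i]; xmm[j] <- x[j] - hv[j]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
          (4 * hv[i] * hv[j])
      }
    }
  }
  (H + t(H)) / 2
}

# Jacobian of (theta_orig, beta_orig) w.r.t. internal (tpar, beta_std)
param_jacobian <- function(par, K, p, xc, xs, idx_t, idx_b) {
  m <- K - 1L + p
  J <- matrix(0, m, m)
  # theta_std_k = t1 + sum_{j<=k, j>=2} exp(tpar_j)
  for (k in seq_len(K - 1L)) {
    J[k, 1] <- 1
    if (K > 2L && k >= 2L) {
      for (j in 2:k) J[k, j] <- exp(par[idx_t][j])
    }
  }
  if (p) {
    # theta_orig = theta_std + sum_j beta_std_j * xc_j / xs_j
    for (k in seq_len(K - 1L)) {
      J[k, (K - 1L) + seq_len(p)] <- xc / xs
    }
    # beta_orig = beta_std / xs
    for (j in seq_len(p)) J[(K - 1L) + j, (K - 1L) + j] <- 1 / xs[j]
  }
  J
}

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  Tm <- matrix(0, n, n)
  Tm[cbind(i, i + 1L)] <- b
  Tm[cbind(i + 1L, i)] <- b
  e <- eigen(Tm, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  weights <- sqrt(pi) * e$vectors[1, ord]^2
  list(nodes = nodes, weights = weights)
}
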