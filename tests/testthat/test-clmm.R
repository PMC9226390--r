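sim_re_dataset <- function(J, nt, beta, thresholds, sd_u, seed) {
  set.seed(seed)
  g <- rep(seq_len(J), each = nt)
  x <- rnorm(J * nt)
  u <- rnorm(J, 0, sd_u)
  y <- sim_po_data(J * nt, beta, matrix(x), thresholds, group = g, u = u)
  data.frame(y = y, x = x, p = factor(g))
}

test_that("mixed fit collapses to the fixed-effect fit without heterogeneity", {
  d <- sim_re_dataset(30, 40, 0.5, c(-0.8, 0.4, 1.3), sd_u = 0, seed = 41)
  fm <- cumlink(y ~ x + (1 | p), d)
  fc <- cumlink(y ~ x, d)
  expect_lt(abs(fm$logLik - fc$logLik), 0.1)
  expect_lt(fm$re_sd[["(Intercept)"]], 0.15)
  expect_equal(unname(fm$beta), unname(fc$beta), tolerance = 0.02)
})

test_that("Laplace recovers a planted random-intercept SD", {
  errs <- vapply(1:5, function(r) {
    d <- sim_re_dataset(40, 60, 0.5, c(-0.8, 0.4, 1.3), sd_u = 0.7,
                        seed = 50 + r)
    fm <- cumlink(y ~ x + (1 | p), d)
    abs(fm$re_sd[["(Intercept)"]] - 0.7) / 0.7
  }, numeric(1))
  expect_lt(mean(errs), 0.5)   # average relative error across replicates
})

test_that("Laplace and 15-node adaptive quadrature agree on the loglik", {
  d <- sim_re_dataset(35, 50, 0.4, c(-1, 0.5), sd_u = 0.8, seed = 61)
  fl <- cumlink(y ~ x + (1 | p), d, method = "laplace")
  fq <- cumlink(y ~ x + (1 | p), d, method = "agq", nagq = 15)
  expect_lt(abs(fl$logLik - fq$logLik), 0.5)
  expect_equal(unname(fl$beta), unname(fq$beta), tolerance = 0.05)
})

test_that("quadrature is refused for random-slope models", {
  d <- sim_re_dataset(10, 20, 0.3, c(-0.5, 0.5), sd_u = 0.5, seed = 62)
  d$t <- rep(seq_len(20), 10) / 20
  expect_error(cumlink(y ~ x + (1 + t | p), d, method = "agq"),
               "random-intercept")
})

test_that("correlated random slope fits report a 2x2 covariance", {
  set.seed(63)
  J <- 30; nt <- 60
  g <- rep(seq_len(J), each = nt)
  t <- rep(seq(-1, 1, length.out = nt), J)
  x <- rnorm(J * nt)
  u0 <- rnorm(J, 0, 0.6)
  u1 <- rnorm(J, 0, 0.5)
  eta <- 0.4 * x + u0[g] + u1[g] * t
  cum <- vapply(c(-0.8, 0.4, 1.3), function(th) plogis(th - eta),
                numeric(J * nt))
  y <- factor(rowSums(sweep(cbind(cum, 1), 1, runif(J * nt), "<")) + 1)
  d <- data.frame(y = y, x = x, t = t, p = factor(g))
  f <- cumlink(y ~ x + t + (1 + t | p), d)
  expect_equal(dim(f$re_covariance), c(2L, 2L))
  expect_true(all(eigen(f$re_covariance)$values > -1e-8))
  expect_lt(abs(f$re_sd[["(Intercept)"]] - 0.6), 0.3)
  expect_lt(abs(f$re_sd[["t"]] - 0.5), 0.3)
  # conditional modes correlate with the planted effects
  expect_gt(cor(f$ranef[, "(Intercept)"], u0), 0.6)
  expect_gt(cor(f$ranef[, "t"], u1), 0.5)
})

test_that("simulate() round-trips the fitted generative model", {
  d <- sim_re_dataset(35, 60, 0.6, c(-0.7, 0.6), sd_u = 0.7, seed = 64)
  f <- cumlink(y ~ x + (1 | p), d)
  sims <- simulate(f, nsim = 1, seed = 9, newdata = d)
  d2 <- d
  d2$y <- sims[[1]]
  f2 <- cumlink(y ~ x + (1 | p), d2)
  expect_lt(abs(f2$beta[["x"]] - f$beta[["x"]]),
            4 * sqrt(diag(f2$vcov))[["x"]])
})

test_that("planted fixed effect is detected at study scale", {
  # one replicate of the study-scale recovery check (the acceptance suite
  # runs the full replicate set)
  set.seed(65)
  J <- 41; nt <- 120
  g <- rep(seq_len(J), each = nt)
  audio <- rep(rep(c(0, 1), each = nt / 2), J)
  u <- rnorm(J, 0, 0.7)
  y <- sim_po_data(J * nt, 0.3, matrix(audio), c(-1.5, -0.5, 0.5, 1.5),
                   group = g, u = u)
  d <- data.frame(y = y, audio = audio, p = factor(g))
  f <- cumlink(y ~ audio + (1 | p), d)
  z <- f$beta[["audio"]] / sqrt(diag(f$vcov))[["audio"]]
  expect_lt(2 * pnorm(-abs(z)), 0.05)
  expect_lt(abs(f$beta[["audio"]] - 0.3), 4 * sqrt(diag(f$vcov))[["audio"]])
})
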