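# Moderation, mediation, moderated mediation: recovery of known truths,
# closed-form identities, bootstrap determinism.

test_that("moderation rejects degenerate designs", {
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_error(fit_moderation(x, rep(1, 50), y), "constant")
  expect_error(fit_moderation(x[1:5], rnorm(5), y[1:5]), ">= 10")
})

test_that("moderation recovers a known interaction and its F identity", {
  set.seed(101)
  n <- 5000
  x <- rnorm(n); w <- rnorm(n)
  y <- 0.2 + 0.4 * x + 0.3 * w + 0.5 * x * w + rnorm(n)
  fit <- fit_moderation(x, w, y)
  b3 <- fit$coef$estimate[4]; se3 <- fit$coef$se[4]
  expect_lt(abs(b3 - 0.5), 3 * se3)
  # F statistic equals its closed form on any fixture
  f_oracle <- (fit$r2_full - fit$r2_reduced) /
    ((1 - fit$r2_full) / (fit$n - 4))
  expect_equal(fit$f, f_oracle)
  expect_equal(fit$df, c(1L, n - 4L))
  # simple slopes at +/- 1 SD differ in the direction of the interaction
  expect_gt(fit$simple_slopes$slope[2], fit$simple_slopes$slope[1])
  # delta-method slope matches refitting at a shifted moderator
  w0 <- fit$w_sd
  slope_hat <- fit$coef$estimate[2] + fit$coef$estimate[4] * w0
  expect_equal(fit$simple_slopes$slope[2], slope_hat)
})

test_that("interaction contrast d isolates the interaction term", {
  set.seed(2)
  n <- 800
  x <- rnorm(n); w <- rnorm(n)
  y <- 1 + 0.5 * x + 0.8 * w + rnorm(n)  # no interaction
  fit0 <- fit_moderation(x, w, y)
  d0 <- simple_slope_contrast_d(fit0)
  b3 <- fit0$coef$estimate[4]
  expect_equal(d0, b3 * 2 * fit0$w_sd * fit0$x_sd / fit0$sigma)
  # doubling b3 doubles d (linearity in the interaction coefficient)
  y2 <- y + 0.4 * x * w
  y3 <- y + 0.8 * x * w
  fit2 <- fit_moderation(x, w, y2); fit3 <- fit_moderation(x, w, y3)
  extra2 <- simple_slope_contrast_d(fit2) * fit2$sigma - d0 * fit0$sigma
  extra3 <- simple_slope_contrast_d(fit3) * fit3$sigma - d0 * fit0$sigma
  expect_equal(extra3 / extra2, 2, tolerance = 1e-6)
  # hand-computed value on a fully specified fixture
  expect_equal(simple_slope_contrast_d(fit2, x_probe = 1, w_hi = 2, w_lo = -1),
               fit2$coef$estimate[4] * 3 / fit2$sigma)
})

test_that("incremental regression matches hierarchical R2 accounting", {
  set.seed(3)
  n <- 400
  x <- rnorm(n); z <- rnorm(n); y <- 0.6 * x + rnorm(n)
  inc <- incremental_regression(x, z, y)
  expect_lt(inc$delta_r2, 0.02)  # z is noise
  expect_equal(inc$df, c(1L, n - 3L))
  expect_error(incremental_regression(x, x, y), "collinear|singular")
  # constructed identity: z = residual of y on x completes the fit
  z_res <- resid(lm(y ~ x))
  inc2 <- suppressWarnings(incremental_regression(x, z_res, y))
  expect_equal(inc2$r2_full, 1)
})

test_that("mediation identities hold and bootstrap is deterministic", {
  set.seed(4)
  n <- 300
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m + 0.3 * x + rnorm(n)
  f1 <- fit_mediation(x, m, y, n_boot = 1000, seed = 77)
  f2 <- fit_mediation(x, m, y, n_boot = 1000, seed = 77)
  expect_identical(f1$indirect_ci, f2$indirect_ci)
  expect_identical(f1$draws, f2$draws)
  # total-effect decomposition holds exactly in OLS with complete data
  expect_equal(f1$c, f1$c_prime + f1$a * f1$b)
  expect_true(f1$indirect_ci[1] <= f1$indirect &
                f1$indirect <= f1$indirect_ci[2])
  # identity case y == m: indirect = a, direct = 0
  f3 <- fit_mediation(x, m, m, n_boot = 1000, seed = 5)
  expect_equal(f3$b, 1)
  expect_equal(f3$c_prime, 0, tolerance = 1e-10)
  expect_equal(f3$indirect, f3$a)
  expect_error(fit_mediation(x, m, y, n_boot = 10, seed = 1), "1000")
  expect_error(fit_mediation(x, m, y, n_boot = 1000), "seed")
})

test_that("mediation recovers a known indirect effect", {
  set.seed(6)
  n <- 2000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m + 0.2 * x + rnorm(n)
  fit <- fit_mediation(x, m, y, n_boot = 1000, seed = 12)
  expect_lt(abs(fit$indirect - 0.2), 3 * fit$indirect_se)
})

test_that("null-mediator CI covers zero at roughly nominal rate", {
  # m independent of x: indirect effect is 0; the 95% percentile CI should
  # cover 0 in close to 95% of replicates
  set.seed(13)
  n_rep <- 120
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 120
    x <- rnorm(n); m <- rnorm(n); y <- 0.3 * x + rnorm(n)
    ci <- fit_mediation(x, m, y, n_boot = 1000, seed = 1000 + r)$indirect_ci
    cover[r] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gte(mean(cover), 0.90)
})

test_that("moderated mediation: constant paths give a flat probe grid", {
  set.seed(14)
  n <- 600
  x <- rnorm(n); w <- rnorm(n); v <- rnorm(n)
  m <- 0.5 * x + rnorm(n)          # a3 = 0
  y <- 0.4 * m + 0.2 * x + rnorm(n)  # b3 = 0
  fit <- fit_moderated_mediation(x, w, m, v, y, n_boot = 1000, seed = 3)
  est <- fit$conditional$estimate
  expect_lt(diff(range(est)), 0.05)
  # equivalence with plain mediation on the a1/b1 paths
  med <- fit_mediation(x, m, y, n_boot = 1000, seed = 3)
  expect_equal(fit$a_model$estimate[2], med$a, tolerance = 0.02)
  expect_equal(fit$y_model$estimate[3], med$b, tolerance = 0.02)
})

test_that("moderated mediation flags only jointly-high probe cells", {
  set.seed(15)
  n <- 5000
  x <- rnorm(n); w <- rnorm(n); v <- rnorm(n)
  m <- 0.3 * x + 0.3 * x * w + rnorm(n)        # a1 = a3 = 0.3
  y <- 0.3 * m + 0.3 * m * v + 0.2 * x + rnorm(n)  # b1 = b3 = 0.3
  sw <- sd(w); sv <- sd(v)
  fit <- fit_moderated_mediation(
    x, w, m, v, y, n_boot = 1000, seed = 8,
    probes = list(w = c(-sw, sw), v = c(-sv, sv)))
  cond <- fit$conditional
  hi_hi <- cond$excludes_zero[cond$w_probe > 0 & cond$v_probe > 0]
  lo_lo <- cond$excludes_zero[cond$w_probe < 0 & cond$v_probe < 0]
  expect_true(hi_hi)
  expect_false(lo_lo)  # (a1 - a3 sd)(b1 - b3 sd) ~ 0: CI straddles zero
  # point estimates follow the closed form (a1+a3 w0)(b1+b3 v0)
  a <- fit$a_model$estimate; b <- fit$y_model$estimate
  expect_equal(cond$estimate,
               (a[2] + a[4] * cond$w_probe) * (b[3] + b[5] * cond$v_probe))
  # all-zero outcome gives all-zero coefficients
  fit0 <- fit_moderated_mediation(x, w, m, v, rep(0, n), n_boot = 1000,
                                  seed = 9)
  expect_true(all(abs(fit0$y_model$estimate) < 1e-10))
  expect_true(all(abs(fit0$conditional$estimate) < 1e-10))
})

test_that("the cross-moderator variant model is reported alongside", {
  set.seed(16)
  n <- 400
  x <- rnorm(n); w <- rnorm(n); v <- rnorm(n)
  m <- 0.4 * x + rnorm(n)
  y <- 0.4 * m + 0.1 * m * w * v + rnorm(n)
  fit <- fit_moderated_mediation(x, w, m, v, y, n_boot = 1000, seed = 4)
  expect_false(is.null(fit$variant_wv))
  expect_identical(fit$variant_wv$term,
                   c("(Intercept)", "x", "m", "v", "m:v", "w:v", "m:w:v"))
  mwv <- fit$variant_wv[fit$variant_wv$term == "m:w:v", ]
  expect_lt(abs(mwv$estimate - 0.1), 3 * mwv$se)
})
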