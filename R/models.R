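# Moderation, mediation and moderated mediation with percentile-bootstrap
# inference. Point estimates come from OLS (stats::lm); bootstrap resamples
# use closed-form normal equations for speed. Missing data are handled
# listwise within each model (available-case analysis, no imputation).

drop_incomplete <- function(...) {
  df <- data.frame(...)
  df[complete.cases(df), , drop = FALSE]
}

check_nonconstant <- function(v, name) {
  if (sd(v) == 0) stop("'", name, "' is constant; model not identifiable")
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
}

# percentile CI on bootstrap draws
boot_ci <- function(draws, level) {
  lo <- (1 - level) / 2
  unname(quantile(draws, c(lo, 1 - lo), na.rm = TRUE, type = 7))
}

#' Moderation model (interaction regression) with simple slopes
#'
#' Fits `y ~ x + w + x:w` with `x` and `w` mean-centered before the product
#' (so lower-order coefficients are simple effects at the means). Reports the
#' interaction's increment in explained variance over the main-effects model
#' via an F test with df (1, n - 4), and simple slopes of `y` on `x` probed
#' at moderator values (default mean +/- 1 SD) with delta-method SEs.
#'
#' @param x Predictor scores.
#' @param w Moderator scores.
#' @param y Outcome scores.
#' @param probes Moderator probe values on the centered scale (`NULL` =
#'   `c(-sd(w), +sd(w))`).
#' @param level Confidence level for coefficient CIs.
#' @return An object of class `pcr_moderation` with elements `coef`
#'   (b0..b3 with SE, t, p), `delta_r2`, `f`, `df`, `p_delta_r2`,
#'   `simple_slopes` (tibble), `sigma` (residual SD), `n`, and centering
#'   means/SDs.
#' @export
fit_moderation <- function(x, w, y, probes = NULL, level = 0.95) {
  df <- drop_incomplete(x = x, w = w, y = y)
  n <- nrow(df)
  if (n < 10L) stop("need >= 10 complete cases, got ", n)
  check_nonconstant(df$x, "x"); check_nonconstant(df$w, "w")
  xc <- df$x - mean(df$x)
  wc <- df$w - mean(df$w)
  X <- cbind(`(Intercept)` = 1, x = xc, w = wc, `x:w` = xc * wc)
  check_full_rank(X)
  fit_full <- lm(df$y ~ xc + wc + I(xc * wc))
  fit_red <- lm(df$y ~ xc + wc)
  r2_full <- summary(fit_full)$r.squared
  r2_red <- summary(fit_red)$r.squared
  delta_r2 <- r2_full - r2_red
  f <- (delta_r2 / 1) / ((1 - r2_full) / (n - 4))
  p_delta <- pf(f, 1, n - 4, lower.tail = FALSE)
  b <- coef(fit_full)
  V <- vcov(fit_full)
  se <- sqrt(diag(V))
  tval <- b / se
  pval <- 2 * pt(-abs(tval), n - 4)
  coefs <- tibble(
    term = c("b0", "b1_x", "b2_w", "b3_xw"),
    estimate = unname(b), se = unname(se), t = unname(tval), p = unname(pval)
  )
  if (is.null(probes)) probes <- c(-sd(df$w), sd(df$w))
  ss <- lapply(probes, function(w0) {
    slope <- b[2] + b[4] * w0
    se_s <- sqrt(V[2, 2] + w0^2 * V[4, 4] + 2 * w0 * V[2, 4])
    t_s <- slope / se_s
    tibble(w_probe = w0, slope = unname(slope), se = se_s,
           t = unname(t_s), p = unname(2 * pt(-abs(t_s), n - 4)))
  })
  structure(
    list(
      coef = coefs, delta_r2 = delta_r2, f = f, df = c(1L, n - 4L),
      p_delta_r2 = p_delta, r2_full = r2_full, r2_reduced = r2_red,
      simple_slopes = do.call(rbind, ss), sigma = summary(fit_full)$sigma,
      n = n, level = level,
      x_mean = mean(df$x), x_sd = sd(df$x),
      w_mean = mean(df$w), w_sd = sd(df$w)
    ),
    class = "pcr_moderation"
  )
}

#' Interaction-contrast effect size for a moderation model
#'
#' Standardized difference between model-implied outcomes at a probe value
#' of the (centered) predictor under high versus low moderator values,
#' isolating the interaction term:
#' `d = b3 * (w_hi - w_lo) * x_probe / sigma_residual`.
#' The moderator's main effect is excluded so that `d = 0` whenever the
#' interaction is null.
#'
#' @param model A `pcr_moderation`.
#' @param x_probe Predictor probe on the centered scale (default +1 SD).
#' @param w_hi,w_lo Moderator probes on the centered scale (defaults
#'   +/- 1 SD).
#' @return Effect size d (signed).
#' @export
simple_slope_contrast_d <- function(model, x_probe = NULL,
                                    w_hi = NULL, w_lo = NULL) {
  stopifnot(inherits(model, "pcr_moderation"))
  if (is.null(x_probe)) x_probe <- model$x_sd
  if (is.null(w_hi)) w_hi <- model$w_sd
  if (is.null(w_lo)) w_lo <- -model$w_sd
  b3 <- model$coef$estimate[model$coef$term == "b3_xw"]
  b3 * (w_hi - w_lo) * x_probe / model$sigma
}

#' Hierarchical (incremental) regression
#'
#' Tests whether `z` adds explained variance in `y` beyond `x`:
#' `y ~ x` versus `y ~ x + z`, F test with df (1, n - 3).
#'
#' @param x Baseline predictor.
#' @param z Incremental predictor.
#' @param y Outcome.
#' @return List with `delta_r2`, `f`, `df`, `p`, `r2_full`, `r2_reduced`,
#'   `n`.
#' @export
incremental_regression <- function(x, z, y) {
  df <- drop_incomplete(x = x, z = z, y = y)
  n <- nrow(df)
  if (n < 10L) stop("need >= 10 complete cases, got ", n)
  X <- cbind(`(Intercept)` = 1, x = df$x, z = df$z)
  check_full_rank(X)
  fit_full <- lm(y ~ x + z, data = df)
  fit_red <- lm(y ~ x, data = df)
  r2_full <- summary(fit_full)$r.squared
  r2_red <- summary(fit_red)$r.squared
  delta_r2 <- r2_full - r2_red
  f <- delta_r2 / ((1 - r2_full) / (n - 3))
  list(delta_r2 = delta_r2, f = f, df = c(1L, n - 3L),
       p = pf(f, 1, n - 3, lower.tail = FALSE),
       r2_full = r2_full, r2_reduced = r2_red, n = n)
}

# closed-form OLS of y on (1, x): returns slope
slope1 <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

# closed-form OLS of y on (1, x1, x2): returns c(b_x1, b_x2)
slope2 <- function(x1, x2, y) {
  x1c <- x1 - mean(x1); x2c <- x2 - mean(x2); yc <- y - mean(y)
  s11 <- sum(x1c * x1c); s22 <- sum(x2c * x2c); s12 <- sum(x1c * x2c)
  det <- s11 * s22 - s12 * s12
  c((s22 * sum(x1c * yc) - s12 * sum(x2c * yc)) / det,
    (s11 * sum(x2c * yc) - s12 * sum(x1c * yc)) / det)
}

#' Simple mediation with percentile-bootstrap confidence intervals
#'
#' Paths: `a` from `m ~ x`; `b` and `c'` (direct effect) from `y ~ x + m`;
#' total effect `c` from `y ~ x`. The indirect effect `a*b` and the ratio of
#' indirect to direct effect get nonparametric case-resampling percentile
#' CIs. Zero-variance resamples are redrawn (and counted). In OLS with
#' complete data `c = c' + a*b` exactly; two "proportion mediated"
#' conventions are reported: `a*b / c` and `a*b / (a*b + c')`.
#'
#' @param x,m,y Predictor, mediator, outcome scores.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed RNG seed (bootstrap is deterministic given it).
#' @param level Confidence level (use 0.9833 for a Bonferroni-corrected 95%
#'   CI over three model families).
#' @return An object of class `pcr_mediation`: paths `a`, `b`, `c`,
#'   `c_prime`, `indirect` (+ `_se`, `_ci`), `ratio_indirect_direct`
#'   (+ `_se`, `_ci`), `prop_mediated_total`, `prop_mediated_sum`, `n`,
#'   `n_redrawn`, and the bootstrap draws.
#' @export
fit_mediation <- function(x, m, y, n_boot = 10000L, seed, level = 0.95) {
  if (missing(seed)) stop("a seed is mandatory for the bootstrap")
  if (n_boot < 1000L) stop("n_boot must be >= 1000")
  df <- drop_incomplete(x = x, m = m, y = y)
  n <- nrow(df)
  if (n < 10L) stop("need >= 10 complete cases, got ", n)
  check_nonconstant(df$x, "x"); check_nonconstant(df$m, "m")
  a <- slope1(df$x, df$m)
  bc <- slope2(df$x, df$m, df$y)
  c_prime <- bc[1]; b <- bc[2]
  c_total <- slope1(df$x, df$y)
  draws <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("indirect", "ratio")))
  n_redrawn <- 0L
  with_local_seed(seed, {
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(df$x[idx]) > 0 && sd(df$m[idx]) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      a_i <- slope1(df$x[idx], df$m[idx])
      bc_i <- slope2(df$x[idx], df$m[idx], df$y[idx])
      draws[i, 1] <- a_i * bc_i[2]
      draws[i, 2] <- a_i * bc_i[2] / bc_i[1]
    }
  })
  structure(
    list(
      a = a, b = b, c = c_total, c_prime = c_prime,
      indirect = a * b,
      indirect_se = sd(draws[, 1]),
      indirect_ci = boot_ci(draws[, 1], level),
      ratio_indirect_direct = a * b / c_prime,
      ratio_se = sd(draws[, 2]),
      ratio_ci = boot_ci(draws[, 2], level),
      prop_mediated_total = a * b / c_total,
      prop_mediated_sum = a * b / (a * b + c_prime),
      n = n, n_boot = n_boot, level = level, seed = seed,
      n_redrawn = n_redrawn, draws = draws
    ),
    class = "pcr_mediation"
  )
}

#' Moderated mediation (first- and second-stage moderation)
#'
#' Mediator model: `m ~ x + w + x:w` (first-stage moderator `w`); outcome
#' model: `y ~ x + m + v + m:v` (second-stage moderator `v`); all variables
#' entering products are mean-centered first. The conditional indirect effect
#' at moderator values (w0, v0) is `(a1 + a3*w0) * (b1 + b3*v0)`, evaluated
#' on a probe grid (default: 25th/50th/75th percentiles of each centered
#' moderator) with percentile-bootstrap CIs sharing one set of resamples
#' across cells.
#'
#' A documented secondary variant of the outcome model additionally enters
#' the moderator product `w:v` and its interaction with the mediator
#' `m:(w:v)`, exposing a single cross-moderator interaction coefficient; its
#' coefficient table is returned under `$variant_wv` but the conditional
#' indirect effects above are always taken from the standard equations.
#'
#' @param x,w,m,v,y Predictor, first-stage moderator, mediator, second-stage
#'   moderator, outcome.
#' @param n_boot Bootstrap resamples (>= 1000).
#' @param seed RNG seed.
#' @param level Confidence level.
#' @param probes Optional list with elements `w` and `v`: probe values on
#'   the centered scales.
#' @return An object of class `pcr_modmed` with `a_model` / `y_model`
#'   coefficient tibbles, a `conditional` tibble (one row per (w0, v0) cell:
#'   estimate, CI, `excludes_zero` flag), `variant_wv`, and metadata.
#' @export
fit_moderated_mediation <- function(x, w, m, v, y, n_boot = 10000L, seed,
                                    level = 0.95, probes = NULL) {
  if (missing(seed)) stop("a seed is mandatory for the bootstrap")
  if (n_boot < 1000L) stop("n_boot must be >= 1000")
  df <- drop_incomplete(x = x, w = w, m = m, v = v, y = y)
  n <- nrow(df)
  if (n < 10L) stop("need >= 10 complete cases, got ", n)
  for (nm in c("x", "w", "m", "v")) check_nonconstant(df[[nm]], nm)
  cen <- function(z) z - mean(z)
  xc <- cen(df$x); wc <- cen(df$w); mc <- cen(df$m); vc <- cen(df$v)
  Xa <- cbind(`(Intercept)` = 1, x = xc, w = wc, `x:w` = xc * wc)
  Xy <- cbind(`(Intercept)` = 1, x = xc, m = mc, v = vc, `m:v` = mc * vc)
  check_full_rank(Xa); check_full_rank(Xy)
  fit_coefs <- function(X, yv) {
    fit <- lm(yv ~ X - 1)
    b <- coef(fit); V <- vcov(fit); se <- sqrt(diag(V))
    dfree <- n - ncol(X)
    tibble(term = colnames(X), estimate = unname(b), se = unname(se),
           t = unname(b / se), p = unname(2 * pt(-abs(b / se), dfree)))
  }
  a_tab <- fit_coefs(Xa, df$m)
  y_tab <- fit_coefs(Xy, df$y)
  # secondary variant: cross-moderator product terms in the outcome model
  Xy_var <- cbind(Xy, `w:v` = wc * vc, `m:w:v` = mc * wc * vc)
  variant <- if (qr(Xy_var)$rank == ncol(Xy_var)) {
    fit_coefs(Xy_var, df$y)
  } else NULL
  if (is.null(probes)) {
    probes <- list(w = unname(quantile(wc, c(0.25, 0.5, 0.75))),
                   v = unname(quantile(vc, c(0.25, 0.5, 0.75))))
  }
  grid <- expand.grid(w0 = probes$w, v0 = probes$v)
  cond_point <- function(a1, a3, b1, b3) {
    (a1 + a3 * grid$w0) * (b1 + b3 * grid$v0)
  }
  est <- cond_point(a_tab$estimate[2], a_tab$estimate[4],
                    y_tab$estimate[3], y_tab$estimate[5])
  draws <- matrix(NA_real_, n_boot, nrow(grid))
  with_local_seed(seed, {
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(df$x[idx]) > 0 && sd(df$w[idx]) > 0 &&
            sd(df$m[idx]) > 0 && sd(df$v[idx]) > 0) break
      }
      xi <- cen(df$x[idx]); wi <- cen(df$w[idx])
      mi <- cen(df$m[idx]); vi <- cen(df$v[idx])
      Xa_i <- cbind(1, xi, wi, xi * wi)
      Xy_i <- cbind(1, xi, mi, vi, mi * vi)
      a_i <- tryCatch(qr.solve(crossprod(Xa_i), crossprod(Xa_i, df$m[idx])),
                      error = function(e) NULL)
      b_i <- tryCatch(qr.solve(crossprod(Xy_i), crossprod(Xy_i, df$y[idx])),
                      error = function(e) NULL)
      if (is.null(a_i) || is.null(b_i)) next
      draws[i, ] <- (a_i[2] + a_i[4] * grid$w0) * (b_i[3] + b_i[5] * grid$v0)
    }
  })
  cis <- t(apply(draws, 2, boot_ci, level = level))
  conditional <- tibble(
    w_probe = grid$w0, v_probe = grid$v0, estimate = est,
    ci_lower = cis[, 1], ci_upper = cis[, 2],
    excludes_zero = cis[, 1] > 0 | cis[, 2] < 0
  )
  structure(
    list(a_model = a_tab, y_model = y_tab, conditional = conditional,
         variant_wv = variant, n = n, n_boot = n_boot, level = level,
         seed = seed, probes = probes),
    class = "pcr_modmed"
  )
}
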