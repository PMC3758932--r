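# Mean causal/effect association scores, paired contrasts, effect sizes and
# Holm-Bonferroni control.

test_that("mean causal/effect association averages present ratings only", {
  rec <- make_record(freqs = c(`1` = 2L, `2` = 3L, `3` = 1L, `5` = 4L),
                     pcr = data.frame(
                       cause_id = c(1, 1, 1, 2, 3, 5),
                       effect_id = c(2, 3, 5, 1, 1, 1),
                       value = c(2, 4, 9, 5, NA, 7)))
  expect_equal(mean_causal_association(rec, 1), mean(c(2, 4, 9)))
  # one incoming rating skipped by intention: only 5 and 7 count
  expect_equal(mean_effect_association(rec, 1), 6)
  # single present rating
  expect_equal(mean_causal_association(rec, 2), 5)
  # no endorsed partners rated
  rec2 <- make_record(freqs = c(`4` = 3L))
  expect_true(is.na(mean_causal_association(rec2, 4)))
  expect_error(mean_causal_association(rec, 99), "unknown symptom")
  # all-zero ratings average to zero, and scope restricts partners
  rec3 <- make_record(freqs = c(`5` = 1L, `12` = 1L, `13` = 1L),
                      pcr = data.frame(cause_id = c(5, 5, 12, 13),
                                       effect_id = c(12, 13, 5, 5),
                                       value = c(0, 0, 8, 2)))
  expect_equal(mean_causal_association(rec3, 5), 0)
  expect_equal(mean_effect_association(rec3, 5, scope = "DEP"), 5)
})

test_that("subset-to-subset PCR composites average within participant", {
  rec <- make_record(freqs = c(`1` = 2L, `2` = 1L, `13` = 3L),
                     pcr = data.frame(cause_id = c(1, 2, 13, 13, 1, 2),
                                      effect_id = c(13, 13, 1, 2, 2, 1),
                                      value = c(6, 3, 2, 1, 9, 9)))
  expect_equal(subset_pcr_score(rec, "ANX", "DEP"), mean(c(6, 3)))
  expect_equal(subset_pcr_score(rec, "DEP", "ANX"), mean(c(2, 1)))
  expect_true(is.na(subset_pcr_score(rec, "REEXP", "DEP")))
})

test_that("d-from-t convention and bounds behave as specified", {
  expect_equal(cohens_d_from_t(4.95, 112, digits = 2), 0.47)
  expect_equal(cohens_d_from_t(6.74, 195, digits = 2), 0.48)
  expect_equal(cohens_d_from_t(3.78, 137, digits = 2), 0.32)
  expect_equal(cohens_d_from_t(0, 50), 0)
  expect_equal(cohens_d_from_t(-2, 3), 1)  # |t|/sqrt(df+1)
  expect_error(cohens_d_from_t(1, 0), "df")
})

test_that("paired cause-vs-effect contrast matches the direct formula", {
  # 5-participant fixture, same endorsed pair everywhere
  vals_c <- c(6, 4, 7, 5, 8)
  vals_e <- c(2, 3, 5, 1, 4)
  recs <- lapply(1:5, function(i) {
    make_record(sprintf("p%d", i), c(`1` = 2L, `2` = 2L),
                pcr = data.frame(cause_id = c(1, 2), effect_id = c(2, 1),
                                 value = c(vals_c[i], vals_e[i])))
  })
  names(recs) <- sprintf("p%d", 1:5)
  res <- cause_effect_comparison(recs, 1)
  d <- vals_c - vals_e
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_oracle)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 4))
  expect_equal(res$r_ec, cor(vals_c, vals_e))
  expect_equal(res$d, abs(t_oracle) / sqrt(5))
  # symptom 2's contrast is the mirror image: t negated
  res2 <- cause_effect_comparison(recs, 2)
  expect_equal(res2$t, -res$t)
})

test_that("degenerate paired contrasts are handled explicitly", {
  recs <- lapply(1:3, function(i) {
    make_record(sprintf("p%d", i), c(`1` = 1L, `2` = 1L),
                pcr = data.frame(cause_id = c(1, 2), effect_id = c(2, 1),
                                 value = c(4, 4)))
  })
  names(recs) <- sprintf("p%d", 1:3)
  res <- cause_effect_comparison(recs, 1)
  expect_true(res$defined)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # constant non-zero difference: undefined marker, not an infinite t
  recs2 <- lapply(1:3, function(i) {
    make_record(sprintf("p%d", i), c(`1` = 1L, `2` = 1L),
                pcr = data.frame(cause_id = c(1, 2), effect_id = c(2, 1),
                                 value = c(6, 2)))
  })
  names(recs2) <- sprintf("p%d", 1:3)
  expect_false(cause_effect_comparison(recs2, 1)$defined)
  # fewer than 2 complete pairs
  expect_false(cause_effect_comparison(recs[1], 1)$defined)
})

test_that("Holm step-down equals its brute-force definition", {
  hb <- holm_bonferroni(runif(40), alpha = 0.05)
  expect_equal(hb$bonferroni_threshold, 0.00125)
  expect_equal(holm_bonferroni(0.3, alpha = 0.05)$bonferroni_threshold, 0.05)
  expect_error(holm_bonferroni(numeric(0)), "non-empty")
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:50) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    hb <- holm_bonferroni(p, alpha)
    expect_identical(hb$reject, oracle_holm(p, alpha))
    if (any(hb$reject)) {
      expect_equal(hb$obtained_threshold, max(p[hb$reject]))
    } else {
      expect_true(is.na(hb$obtained_threshold))
    }
  }
})

test_that("Holm rejections sit between Bonferroni and unadjusted", {
  set.seed(8)
  for (rep in 1:30) {
    p <- runif(sample(2:20, 1))
    alpha <- 0.05
    hb <- holm_bonferroni(p, alpha)
    bonf <- p <= alpha / length(p)
    expect_true(all(hb$reject[bonf]))        # superset of Bonferroni
    expect_true(all(p[hb$reject] <= alpha))  # subset of unadjusted
  }
})

test_that("swapping all PCR directions negates the paired t", {
  sim <- simulate_population(simulation_config(n_participants = 40, seed = 5))
  swapped <- lapply(sim$records, function(rec) {
    rec$pcr <- t(rec$pcr)
    rec$pcr_status <- t(rec$pcr_status)
    rec
  })
  for (sym in c(2L, 13L)) {
    a <- cause_effect_comparison(sim$records, sym)
    b <- cause_effect_comparison(swapped, sym)
    if (a$defined && b$defined && !is.na(a$t)) {
      expect_equal(b$t, -a$t)
      expect_equal(b$p, a$p)
    }
  }
})

test_that("planted asymmetric causes score higher C than E", {
  W <- matrix(0, 40, 40)
  W[1, 2:10] <- 1  # symptom 1 strongly causes many others
  truth <- ground_truth(W, base_rates = rep(0.8, 40), noise = 1.5,
                        pcr_fidelity = 7)
  sim <- simulate_population(
    simulation_config(n_participants = 200, seed = 21, truth = truth))
  res <- cause_effect_comparison(sim$records, 1)
  expect_true(res$defined)
  expect_gt(res$c_mean, res$e_mean)
  expect_lt(res$p, 0.001)
})

test_that("instrument-wide table censors d to corrected-significant rows", {
  sim <- simulate_population(simulation_config(n_participants = 60, seed = 9))
  tab <- cause_effect_table(sim$records)
  expect_identical(nrow(tab), 40L)
  expect_true(all(is.na(tab$d[!tab$significant])))
  expect_true(all(!is.na(tab$d_raw[tab$defined & !is.na(tab$t)])))
  expect_true(all(tab$c_mean >= 0 & tab$c_mean <= 10, na.rm = TRUE))
  expect_true(all(tab$e_mean >= 0 & tab$e_mean <= 10, na.rm = TRUE))
  expect_equal(attr(tab, "bonferroni_threshold"),
               0.05 / sum(!is.na(tab$p)))
})
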