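#!/usr/bin/env Rscript
# Stage 3: moderation, incremental prediction, mediation and moderated
# mediation at the disorder level.
#
# Composites: ANX_FREQ / DEP_FREQ / REEXP_FREQ are subset means of the
# frequency ratings; PCR_A->B is the within-participant mean of the present
# PCR ratings from subset A items to subset B items. The four designs ask,
# in turn, whether PCR scores moderate, increment, or mediate the
# frequency-frequency associations, and whether the shame -> reexperiencing
# -> depression mediation chain is itself moderated by its PCR scores.
# Bootstrap CIs use 10,000 resamples at the Bonferroni-corrected 95% level
# (98.33%), three model families being tested.

suppressPackageStartupMessages(library(pcrnet))
catalog <- default_catalog()
records <- load_pcr_table("results/pcr.csv",
                          load_frequency_table("results/frequencies.csv",
                                               catalog))
seed <- 20260921L
level <- 0.9833
n_boot <- 10000L

num <- function(f) vapply(records, f, numeric(1))
anx <- num(function(r) subset_frequency_score(r, "ANX", catalog))
dep <- num(function(r) subset_frequency_score(r, "DEP", catalog))
rex <- num(function(r) subset_frequency_score(r, "REEXP", catalog))
shame <- num(function(r) {
  f <- r$frequencies[25L]; if (is.na(f)) NA_real_ else as.numeric(f)
})
pcr_anx_dep <- num(function(r) subset_pcr_score(r, "ANX", "DEP", catalog))
pcr_rex_dep <- num(function(r) subset_pcr_score(r, "REEXP", "DEP", catalog))
pcr_shame_rex <- num(function(r) {
  subset_pcr_score(r, 25L, catalog_subset(catalog, "REEXP"), catalog)
})

# -- does PCR_ANX->DEP moderate the ANX_FREQ -> DEP_FREQ association? ------
mod <- fit_moderation(anx, pcr_anx_dep, dep, level = level)
cat(sprintf(
  "Moderation: delta-R2 = %.3f, F(1,%d) = %.2f, p = %.4f (n = %d)\n",
  mod$delta_r2, mod$df[2], mod$f, mod$p_delta_r2, mod$n))
ss <- mod$simple_slopes
cat(sprintf("  simple slope at -1 SD: b = %.3f (SE %.3f); at +1 SD: b = %.3f (SE %.3f)\n",
            ss$slope[1], ss$se[1], ss$slope[2], ss$se[2]))
cat(sprintf("  interaction contrast at +1 SD of ANX_FREQ: d = %.2f\n",
            simple_slope_contrast_d(mod)))

# -- does PCR_ANX->DEP increment prediction beyond ANX_FREQ? ---------------
inc <- incremental_regression(anx, pcr_anx_dep, dep)
cat(sprintf("Incremental: delta-R2 = %.3f, F(1,%d) = %.2f, p = %.4f\n",
            inc$delta_r2, inc$df[2], inc$f, inc$p))

# -- does REEXP_FREQ mediate SHAME_FREQ -> DEP_FREQ? -----------------------
med <- fit_mediation(shame, rex, dep, n_boot = n_boot, seed = seed,
                     level = level)
cat(sprintf(
  "Mediation: indirect = %.3f (SE %.3f), %.2f%% CI [%.3f, %.3f], n = %d\n",
  med$indirect, med$indirect_se, level * 100,
  med$indirect_ci[1], med$indirect_ci[2], med$n))
cat(sprintf("  ratio indirect/direct = %.3f (SE %.3f), CI [%.3f, %.3f]\n",
            med$ratio_indirect_direct, med$ratio_se,
            med$ratio_ci[1], med$ratio_ci[2]))
cat(sprintf("  proportion mediated: %.1f%% of total (%.1f%% of |ab|+|c'| sum)\n",
            100 * med$prop_mediated_total, 100 * med$prop_mediated_sum))

# -- is that mediation moderated by PCR_SHAME->REEXP and PCR_REEXP->DEP? ---
mm <- fit_moderated_mediation(shame, pcr_shame_rex, rex, pcr_rex_dep, dep,
                              n_boot = n_boot, seed = seed, level = level)
cat(sprintf("Moderated mediation (n = %d): conditional indirect effects\n",
            mm$n))
cond <- mm$conditional
for (i in seq_len(nrow(cond))) {
  cat(sprintf("  w0 = %+.2f, v0 = %+.2f: %.4f [%.4f, %.4f]%s\n",
              cond$w_probe[i], cond$v_probe[i], cond$estimate[i],
              cond$ci_lower[i], cond$ci_upper[i],
              if (cond$excludes_zero[i]) " *" else ""))
}

out <- list(
  moderation = list(delta_r2 = mod$delta_r2, f = mod$f, df = mod$df,
                    p = mod$p_delta_r2, n = mod$n,
                    simple_slopes = mod$simple_slopes,
                    contrast_d = simple_slope_contrast_d(mod)),
  incremental = inc,
  mediation = list(a = med$a, b = med$b, c = med$c, c_prime = med$c_prime,
                   indirect = med$indirect, indirect_se = med$indirect_se,
                   indirect_ci = med$indirect_ci,
                   ratio = med$ratio_indirect_direct,
                   ratio_ci = med$ratio_ci,
                   prop_mediated_total = med$prop_mediated_total,
                   prop_mediated_sum = med$prop_mediated_sum, n = med$n),
  moderated_mediation = list(a_model = mm$a_model, y_model = mm$y_model,
                             conditional = mm$conditional,
                             variant_wv = mm$variant_wv, n = mm$n),
  seed = seed, n_boot = n_boot, level = level
)
jsonlite::write_json(out, "results/models.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")
cat("Wrote results/models.json\n")
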