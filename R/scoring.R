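# Mean causal / effect association scoring and cause-vs-effect contrasts.

scope_ids <- function(scope, catalog) {
  if (identical(scope, "all")) return(1:40)
  catalog_subset(catalog, scope)
}

#' Mean causal association score of a symptom
#'
#' The average of the present PCR ratings a symptom receives as the cause
#' ("how much does X cause Y?") across all rated partner symptoms, optionally
#' restricted to partners in a named subset.
#'
#' @param record A `participant_record`.
#' @param symptom Item id.
#' @param scope `"all"` or a subset name (partner scope).
#' @param catalog A `symptom_catalog`.
#' @return Mean rating in `[0, 10]`, or `NA` when no present ratings exist.
#' @export
mean_causal_association <- function(record, symptom, scope = "all",
                                    catalog = default_catalog()) {
  symptom <- as.integer(symptom)
  if (!symptom %in% 1:40) stop("unknown symptom id ", symptom)
  partners <- setdiff(scope_ids(scope, catalog), symptom)
  vals <- record$pcr[symptom, partners]
  st <- record$pcr_status[symptom, partners]
  vals <- vals[!is.na(st) & st == STATUS_PRESENT]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Mean effect association score of a symptom
#'
#' Mirror of [mean_causal_association()]: the average present PCR rating a
#' symptom receives as the effect ("how much does Y cause X?").
#'
#' @inheritParams mean_causal_association
#' @return Mean rating in `[0, 10]`, or `NA`.
#' @export
mean_effect_association <- function(record, symptom, scope = "all",
                                    catalog = default_catalog()) {
  symptom <- as.integer(symptom)
  if (!symptom %in% 1:40) stop("unknown symptom id ", symptom)
  partners <- setdiff(scope_ids(scope, catalog), symptom)
  vals <- record$pcr[partners, symptom]
  st <- record$pcr_status[partners, symptom]
  vals <- vals[!is.na(st) & st == STATUS_PRESENT]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Subset-to-subset PCR composite within a participant
#'
#' Mean of the present PCR ratings from items of subset `from` to items of
#' subset `to` (e.g. the perceived causal strength of anxiety for
#' depression). `NA` when no such ratings are present.
#'
#' @param record A `participant_record`.
#' @param from,to Subset names or integer id vectors.
#' @param catalog A `symptom_catalog`.
#' @return Mean rating or `NA`.
#' @export
subset_pcr_score <- function(record, from, to, catalog = default_catalog()) {
  fi <- if (is.character(from)) catalog_subset(catalog, from) else as.integer(from)
  ti <- if (is.character(to)) catalog_subset(catalog, to) else as.integer(to)
  sub_v <- record$pcr[fi, ti, drop = FALSE]
  sub_s <- record$pcr_status[fi, ti, drop = FALSE]
  vals <- sub_v[!is.na(sub_s) & sub_s == STATUS_PRESENT]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Effect size d from a paired t statistic
#'
#' The package's d-from-t convention for paired contrasts:
#' `d = |t| / sqrt(df + 1)`, i.e. the standardized mean difference computed
#' from the t statistic and the number of pairs (df + 1).
#'
#' @param t Paired t statistic.
#' @param df Degrees of freedom (pairs - 1), `>= 1`.
#' @param digits Optional rounding for reporting (`NULL` = full precision).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, df, digits = NULL) {
  if (any(df < 1)) stop("df must be >= 1")
  d <- abs(t) / sqrt(df + 1)
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' Holm-Bonferroni step-down multiple-comparison control
#'
#' Standard sequential step-down procedure at family-wise level `alpha`.
#' Also reports the plain Bonferroni threshold `alpha / m` and the obtained
#' threshold, i.e. the largest raw p-value that was rejected.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed;
#'   treated as not rejectable and ignored in `m`).
#' @param alpha Family-wise error level.
#' @return List with `reject` (logical, original order), `p_adjusted`
#'   (Holm-adjusted p-values), `bonferroni_threshold`, `obtained_threshold`
#'   (NA when nothing is rejected), `alpha` and `m`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("p_values must be non-empty")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  ok <- !is.na(p_values)
  m <- sum(ok)
  adj <- rep(NA_real_, length(p_values))
  adj[ok] <- p.adjust(p_values[ok], method = "holm")
  reject <- !is.na(adj) & adj <= alpha
  obtained <- if (any(reject)) max(p_values[reject]) else NA_real_
  list(
    reject = reject,
    p_adjusted = adj,
    bonferroni_threshold = alpha / m,
    obtained_threshold = obtained,
    alpha = alpha,
    m = m
  )
}

#' Cause-vs-effect paired contrast for one symptom
#'
#' Per participant, computes the symptom's mean causal (C) and mean effect
#' (E) association scores; across participants with both defined, runs a
#' paired two-tailed t test of C - E, the Pearson correlation `r_EC` of C and
#' E, and the effect size `d = |t| / sqrt(df + 1)`.
#'
#' Zero-variance differences are special-cased: all-zero differences give
#' t = 0, p = 1; constant non-zero differences are returned as undefined
#' (`defined = FALSE`) rather than an infinite statistic.
#'
#' @param records Named list of `participant_record`.
#' @param symptom Item id.
#' @param scope `"all"` or a subset name.
#' @param catalog A `symptom_catalog`.
#' @return One-row [tibble::tibble()] with columns `symptom_id`, `n`,
#'   `freq_mean`, `freq_sd`, `c_mean`, `c_sd`, `e_mean`, `e_sd`, `r_ec`,
#'   `t`, `df`, `p`, `d`, `defined`.
#' @export
cause_effect_comparison <- function(records, symptom, scope = "all",
                                    catalog = default_catalog()) {
  C <- vapply(records, mean_causal_association, numeric(1),
              symptom = symptom, scope = scope, catalog = catalog)
  E <- vapply(records, mean_effect_association, numeric(1),
              symptom = symptom, scope = scope, catalog = catalog)
  fr <- vapply(records, function(r) {
    f <- r$frequencies[symptom]
    if (is.na(f)) NA_real_ else as.numeric(f)
  }, numeric(1))
  keep <- !is.na(C) & !is.na(E)
  n <- sum(keep)
  base <- tibble(
    symptom_id = as.integer(symptom), n = n,
    freq_mean = mean(fr, na.rm = TRUE), freq_sd = sd(fr, na.rm = TRUE),
    c_mean = NA_real_, c_sd = NA_real_, e_mean = NA_real_, e_sd = NA_real_,
    r_ec = NA_real_, t = NA_real_, df = NA_integer_, p = NA_real_,
    d = NA_real_, defined = FALSE
  )
  if (n < 2L) return(base)
  Ck <- C[keep]; Ek <- E[keep]
  base$c_mean <- mean(Ck); base$c_sd <- sd(Ck)
  base$e_mean <- mean(Ek); base$e_sd <- sd(Ek)
  base$r_ec <- if (sd(Ck) > 0 && sd(Ek) > 0) cor(Ck, Ek) else NA_real_
  diffs <- Ck - Ek
  base$df <- n - 1L
  if (sd(diffs) == 0) {
    if (mean(diffs) == 0) {
      base$t <- 0; base$p <- 1; base$d <- 0; base$defined <- TRUE
    }
    return(base)  # constant non-zero difference: undefined marker
  }
  tt <- t.test(Ck, Ek, paired = TRUE)
  base$t <- unname(tt$statistic)
  base$p <- tt$p.value
  base$d <- cohens_d_from_t(base$t, base$df)
  base$defined <- TRUE
  base
}

#' Instrument-wide cause-vs-effect summary table
#'
#' Runs [cause_effect_comparison()] for every item, applies Holm-Bonferroni
#' control over the defined p-values, and censors `d` to
#' significant-after-correction contrasts (the reporting convention for this
#' table); `d_raw` keeps the uncensored value.
#'
#' @param records Named list of `participant_record`.
#' @param catalog A `symptom_catalog`.
#' @param scope `"all"` or a subset name.
#' @param alpha Family-wise error level.
#' @return A tibble with one row per item plus columns `abbreviation`,
#'   `category`, `significant`, `d_raw`; attributes `bonferroni_threshold`
#'   and `obtained_threshold` carry the correction's thresholds.
#' @export
cause_effect_table <- function(records, catalog = default_catalog(),
                               scope = "all", alpha = 0.05) {
  rows <- lapply(catalog$items$id, function(id) {
    cause_effect_comparison(records, id, scope = scope, catalog = catalog)
  })
  tab <- do.call(rbind, rows)
  tab$abbreviation <- catalog$items$abbreviation[tab$symptom_id]
  tab$category <- catalog$items$category[tab$symptom_id]
  hb <- holm_bonferroni(tab$p, alpha = alpha)
  tab$significant <- hb$reject
  tab$d_raw <- tab$d
  tab$d[!tab$significant] <- NA_real_
  attr(tab, "bonferroni_threshold") <- hb$bonferroni_threshold
  attr(tab, "obtained_threshold") <- hb$obtained_threshold
  tab
}
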