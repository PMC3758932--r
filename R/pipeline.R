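# End-to-end orchestration: simulate (or load) -> score -> regression models
# -> group network -> feedback loops, with one summary report. A single
# global seed is fanned out to per-stage seeds as seed + stage counter
# (simulate +1, models +2, network +3), so stages stay reproducible
# independently of which are enabled.

#' Pipeline configuration
#'
#' @param seed Global seed (mandatory; stages derive their own as
#'   seed + counter).
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector from
#'   `c("simulate", "score", "models", "network", "loops")`.
#' @param n_participants Simulated sample size (ignored when loading files).
#' @param frequencies_csv,pcr_csv Optional input paths; when given, data is
#'   loaded instead of simulated (the `simulate` stage is skipped).
#' @param truth Optional `pcr_ground_truth` for simulation.
#' @param edge_cutoffs Display cutoffs for the group network.
#' @param loop_cutoff Per-participant PCR cutoff for loop analysis.
#' @param max_len Maximum loop length.
#' @param n_boot Bootstrap resamples for the regression models.
#' @param n_perm Permutation networks for centrality nulls.
#' @param ci_level Confidence level (0.9833 = Bonferroni-corrected 95% over
#'   three model families).
#' @param min_edge_n Minimum contributing participants per group-network
#'   edge.
#' @return An object of class `pcr_pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir = "pcrnet_out",
                            stages = c("simulate", "score", "models",
                                       "network", "loops"),
                            n_participants = 288L,
                            frequencies_csv = NULL, pcr_csv = NULL,
                            truth = NULL,
                            edge_cutoffs = c(3, 4.5), loop_cutoff = 4.5,
                            max_len = 4L, n_boot = 2000L, n_perm = 1000L,
                            ci_level = 0.95, min_edge_n = 1L) {
  if (missing(seed)) stop("a seed is mandatory")
  known <- c("simulate", "score", "models", "network", "loops")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (any(edge_cutoffs < 0 | edge_cutoffs > 10) ||
      loop_cutoff < 0 || loop_cutoff > 10) {
    stop("cutoffs must lie in [0, 10]")
  }
  if (max_len < 2L) stop("max_len must be >= 2")
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
         n_participants = as.integer(n_participants),
         frequencies_csv = frequencies_csv, pcr_csv = pcr_csv, truth = truth,
         edge_cutoffs = edge_cutoffs, loop_cutoff = loop_cutoff,
         max_len = as.integer(max_len), n_boot = as.integer(n_boot),
         n_perm = as.integer(n_perm), ci_level = ci_level,
         min_edge_n = as.integer(min_edge_n)),
    class = "pcr_pipeline_config"
  )
}

stage_log <- function(report, stage, t0, ...) {
  info <- list(...)
  info$runtime_s <- round(as.numeric(Sys.time()) - t0, 3)
  report$stages[[stage]] <- info
  message(sprintf("[%s] done in %.2fs (%s)", stage, info$runtime_s,
                  paste(names(info), unlist(lapply(info, paste, collapse = ",")),
                        sep = "=", collapse = "; ")))
  report
}

#' Run the full PCR analysis pipeline
#'
#' Executes the enabled stages over simulated or loaded data, writes each
#' stage's tables (CSV/JSON/GraphML) under `config$out_dir`, and a summary
#' `report.json` / `report.md` with seeds, package version, row counts and
#' runtimes. Stage failures abort with a stage-named error; outputs written
#' so far are preserved.
#'
#' @param config A `pcr_pipeline_config`.
#' @param catalog A `symptom_catalog`.
#' @return The report, invisibly (list).
#' @export
run_pipeline <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "pcr_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pcrnet")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list()
  )
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- data: simulate or load -------------------------------------------
  records <- NULL
  if (!is.null(config$frequencies_csv)) {
    t0 <- as.numeric(Sys.time())
    records <- run_stage("load", function() {
      recs <- load_frequency_table(config$frequencies_csv, catalog)
      if (!is.null(config$pcr_csv)) recs <- load_pcr_table(config$pcr_csv, recs)
      recs
    })
    report <- stage_log(report, "load", t0, n_records = length(records))
  } else if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    sim <- run_stage("simulate", function() {
      truth <- if (is.null(config$truth)) default_ground_truth(catalog) else config$truth
      cfg <- simulation_config(n_participants = config$n_participants,
                               seed = config$seed + 1L, truth = truth)
      simulate_population(cfg)
    })
    records <- sim$records
    write_frequency_table(records, out("frequencies.csv"))
    write_pcr_table(records, out("pcr.csv"))
    jsonlite::write_json(
      list(planted_loops = sim$truth$planted_loops,
           pcr_fidelity = sim$truth$pcr_fidelity, noise = sim$truth$noise),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
    report <- stage_log(report, "simulate", t0, n_records = length(records),
                        seed = config$seed + 1L)
  }
  if (is.null(records)) stop("no data: enable 'simulate' or give input paths")

  # ---- scoring -----------------------------------------------------------
  if ("score" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    tab <- run_stage("score", function() {
      cause_effect_table(records, catalog)
    })
    write.csv(tab, out("cause_effect_table.csv"), row.names = FALSE)
    report <- stage_log(report, "score", t0, n_rows = nrow(tab),
                        n_significant = sum(tab$significant, na.rm = TRUE))
  }

  # ---- regression models -------------------------------------------------
  if ("models" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    models <- run_stage("models", function() {
      anx <- vapply(records, subset_frequency_score, numeric(1),
                    subset = "ANX", catalog = catalog)
      dep <- vapply(records, subset_frequency_score, numeric(1),
                    subset = "DEP", catalog = catalog)
      rex <- vapply(records, subset_frequency_score, numeric(1),
                    subset = "REEXP", catalog = catalog)
      shame <- vapply(records, function(r) {
        f <- r$frequencies[25L]
        if (is.na(f)) NA_real_ else as.numeric(f)
      }, numeric(1))
      pcr_anx_dep <- vapply(records, subset_pcr_score, numeric(1),
                            from = "ANX", to = "DEP", catalog = catalog)
      pcr_rex_dep <- vapply(records, subset_pcr_score, numeric(1),
                            from = "REEXP", to = "DEP", catalog = catalog)
      pcr_shame_rex <- vapply(records, subset_pcr_score, numeric(1),
                              from = 25L, to = catalog_subset(catalog, "REEXP"),
                              catalog = catalog)
      mod <- fit_moderation(anx, pcr_anx_dep, dep)
      inc <- incremental_regression(anx, pcr_anx_dep, dep)
      med <- fit_mediation(shame, rex, dep, n_boot = config$n_boot,
                           seed = config$seed + 2L, level = config$ci_level)
      mm <- fit_moderated_mediation(shame, pcr_shame_rex, rex, pcr_rex_dep,
                                    dep, n_boot = config$n_boot,
                                    seed = config$seed + 2L,
                                    level = config$ci_level)
      list(
        moderation = list(
          delta_r2 = mod$delta_r2, f = mod$f, df = mod$df,
          p = mod$p_delta_r2, n = mod$n,
          simple_slopes = mod$simple_slopes,
          contrast_d = simple_slope_contrast_d(mod)),
        incremental = inc,
        mediation = list(
          a = med$a, b = med$b, c = med$c, c_prime = med$c_prime,
          indirect = med$indirect, indirect_se = med$indirect_se,
          indirect_ci = med$indirect_ci,
          ratio = med$ratio_indirect_direct, ratio_se = med$ratio_se,
          ratio_ci = med$ratio_ci,
          prop_mediated_total = med$prop_mediated_total,
          prop_mediated_sum = med$prop_mediated_sum, n = med$n),
        moderated_mediation = list(
          a_model = mm$a_model, y_model = mm$y_model,
          conditional = mm$conditional, n = mm$n)
      )
    })
    jsonlite::write_json(models, out("models.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    report <- stage_log(report, "models", t0,
                        n_mediation = models$mediation$n,
                        seed = config$seed + 2L)
  }

  # ---- group network -----------------------------------------------------
  if ("network" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    netres <- run_stage("network", function() {
      net <- build_mean_network(records, min_n = config$min_edge_n, catalog)
      thr <- lapply(config$edge_cutoffs, function(cc) {
        threshold_network(net, cc, strict = TRUE)
      })
      rep_cent <- permutation_null(net, n_perm = config$n_perm,
                                   seed = config$seed + 3L)
      list(net = net, thr = thr, centrality = rep_cent)
    })
    write_edge_list(netres$net, out("network_edges.csv"))
    write_network_graphml(netres$net, out("network.graphml"))
    for (i in seq_along(config$edge_cutoffs)) {
      write_edge_list(netres$thr[[i]],
                      out(sprintf("network_edges_cutoff%s.csv",
                                  config$edge_cutoffs[i])))
    }
    write.csv(as.data.frame(netres$centrality), out("centrality.csv"),
              row.names = FALSE)
    xy <- layout_fruchterman_reingold(netres$net, seed = config$seed + 3L)
    write.csv(data.frame(id = rownames(xy), xy), out("layout.csv"),
              row.names = FALSE)
    report <- stage_log(report, "network", t0,
                        n_edges = nrow(netres$net$edges),
                        n_flagged = sum(netres$centrality$extreme),
                        seed = config$seed + 3L)
  }

  # ---- feedback loops ----------------------------------------------------
  if ("loops" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    loopres <- run_stage("loops", function() {
      census <- loop_census(records, cutoff = config$loop_cutoff,
                            max_len = config$max_len, catalog = catalog)
      inv <- symptom_involvement(census, records)
      assoc <- loop_burden_association(census, records)
      list(census = census, involvement = inv, association = assoc)
    })
    write.csv(as.data.frame(loopres$census$participants),
              out("loop_census.csv"), row.names = FALSE)
    write.csv(as.data.frame(loopres$involvement),
              out("loop_involvement.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(association = loopres$association,
           total_incidences = loopres$census$total_incidences,
           unique_loop_types = loopres$census$unique_loop_types),
      out("loop_association.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    report <- stage_log(report, "loops", t0,
                        total_incidences = loopres$census$total_incidences,
                        unique_loop_types = loopres$census$unique_loop_types)
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  md <- c(
    "# pcrnet pipeline report", "",
    paste0("- seed: ", report$seed),
    paste0("- package: pcrnet ", report$package_version),
    paste0("- created: ", report$created), "",
    unlist(lapply(names(report$stages), function(s) {
      info <- report$stages[[s]]
      paste0("- **", s, "** (", info$runtime_s, "s): ",
             paste(names(info), unlist(lapply(info, paste, collapse = ",")),
                   sep = "=", collapse = ", "))
    }))
  )
  writeLines(md, out("report.md"))
  invisible(report)
}
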