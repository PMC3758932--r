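# Per-participant causal feedback loops: thresholded individual networks,
# bounded-length simple-cycle enumeration, per-symptom involvement and the
# loop-count vs symptom-burden association.

#' A participant's thresholded PCR network
#'
#' Nodes are the participant's endorsed symptoms (with their frequency
#' ratings as node attribute); a directed edge (i, j) exists where PCR(i, j)
#' is present and above the cutoff.
#'
#' @param record A `participant_record`.
#' @param cutoff PCR cutoff (default 4.5, strict greater-than).
#' @param strict Use `>` (default) rather than `>=`.
#' @param catalog A `symptom_catalog` (labels only).
#' @return A `symptom_network`.
#' @export
participant_network <- function(record, cutoff = 4.5, strict = TRUE,
                                catalog = default_catalog()) {
  e <- endorsed_items(record)
  pres <- which(!is.na(record$pcr_status) &
                  record$pcr_status == STATUS_PRESENT, arr.ind = TRUE)
  keep <- if (nrow(pres) > 0) {
    w <- record$pcr[pres]
    if (strict) w > cutoff else w >= cutoff
  } else logical(0)
  pres <- pres[keep, , drop = FALSE]
  nodes <- tibble(id = e,
                  frequency = as.numeric(record$frequencies[e]),
                  label = catalog$items$abbreviation[e])
  edges <- tibble(from = pres[, 1], to = pres[, 2],
                  weight = record$pcr[pres], n = 1L)
  symptom_network(nodes, edges)
}

# bounded-depth DFS cycle search over an adjacency list; only nodes with
# index > start are extended, so every cycle is found exactly once in its
# canonical rotation (smallest id first, direction preserved)
dfs_cycles <- function(adj, n, max_len) {
  found <- list()
  nf <- 0L
  path <- integer(max_len)
  visit <- function(start, u, depth) {
    for (v in adj[[u]]) {
      if (v == start && depth >= 2L) {
        nf <<- nf + 1L
        found[[nf]] <<- path[seq_len(depth)]
      } else if (v > start && depth < max_len && !(v %in% path[seq_len(depth)])) {
        path[depth + 1L] <<- v
        visit(start, v, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    if (length(adj[[s]]) == 0L) next
    path[1L] <- s
    visit(s, s, 1L)
  }
  found
}

#' Enumerate bounded-length simple directed cycles
#'
#' All simple directed cycles of length 2 to `max_len` (self-loops cannot
#' occur: PCR is defined only for distinct symptoms). Each cycle is reported
#' once, in canonical rotation: starting at its smallest node id with the
#' edge direction preserved. Output order is deterministic (lexicographic by
#' vertex sequence).
#'
#' @param net A `symptom_network`, or a square logical/numeric adjacency
#'   matrix (nonzero/TRUE = edge; rows are causes).
#' @param max_len Maximum number of distinct symptoms per loop (default 4).
#' @return List of integer vectors (node ids along the cycle).
#' @export
enumerate_cycles <- function(net, max_len = 4L) {
  if (inherits(net, "symptom_network")) {
    ids <- sort(net$nodes$id)
    n <- length(ids)
    adj <- vector("list", n)
    f <- match(net$edges$from, ids)
    t_ <- match(net$edges$to, ids)
    for (i in seq_len(n)) adj[[i]] <- sort(t_[f == i])
  } else {
    A <- as.matrix(net)
    if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
    n <- nrow(A)
    ids <- seq_len(n)
    adj <- lapply(seq_len(n), function(i) which(A[i, ] != 0 & ids != i))
  }
  if (max_len < 2L) return(list())
  raw <- dfs_cycles(adj, n, as.integer(max_len))
  lapply(raw, function(cyc) ids[cyc])
}

#' Census of feedback loops across a population
#'
#' For each participant, builds the thresholded network
#' ([participant_network()]) and enumerates its simple directed cycles of
#' length 2 to `max_len`. Population totals report both semantics of "total
#' loops": `total_incidences` counts (participant, loop) occurrences and
#' `unique_loop_types` counts distinct canonical cycles pooled across
#' participants.
#'
#' @param records Named list of `participant_record`.
#' @param cutoff PCR cutoff (default 4.5).
#' @param max_len Maximum loop length (default 4).
#' @param strict Strict (`>`) thresholding.
#' @param catalog A `symptom_catalog`.
#' @return An object of class `pcr_loop_census`: `participants` tibble
#'   (`participant_id`, `n_symptoms`, `n_edges`, `n_loops`,
#'   `n_pcr_present`), `cycles` (list per participant), `involvement_raw`
#'   (length-40 incidence counts), `total_incidences`, `unique_loop_types`,
#'   and the parameters used.
#' @export
loop_census <- function(records, cutoff = 4.5, max_len = 4L, strict = TRUE,
                        catalog = default_catalog()) {
  n_rec <- length(records)
  cyc_list <- vector("list", n_rec)
  pt <- tibble(
    participant_id = vapply(records, `[[`, character(1), "participant_id"),
    n_symptoms = NA_integer_, n_edges = NA_integer_, n_loops = NA_integer_,
    n_pcr_present = NA_integer_
  )
  involvement <- integer(40L)
  all_keys <- character(0)
  for (i in seq_len(n_rec)) {
    rec <- records[[i]]
    net <- participant_network(rec, cutoff = cutoff, strict = strict,
                               catalog = catalog)
    cycles <- enumerate_cycles(net, max_len = max_len)
    cyc_list[[i]] <- cycles
    pt$n_symptoms[i] <- nrow(net$nodes)
    pt$n_edges[i] <- nrow(net$edges)
    pt$n_loops[i] <- length(cycles)
    pt$n_pcr_present[i] <- n_pcr_present(rec)
    if (length(cycles) > 0) {
      tab <- tabulate(unlist(cycles), nbins = 40L)
      involvement <- involvement + tab
      all_keys <- c(all_keys,
                    vapply(cycles, paste, character(1), collapse = "-"))
    }
  }
  names(cyc_list) <- pt$participant_id
  structure(
    list(participants = pt, cycles = cyc_list,
         involvement_raw = involvement,
         total_incidences = sum(pt$n_loops),
         unique_loop_types = length(unique(all_keys)),
         cutoff = cutoff, max_len = as.integer(max_len), strict = strict),
    class = "pcr_loop_census"
  )
}

#' Per-symptom feedback-loop involvement
#'
#' Raw involvement is the number of (participant, loop) incidences
#' containing the symptom. The default correction divides by the number of
#' participants endorsing the symptom (a symptom can only appear in loops of
#' those who endorse it); `per_frequency_sum` divides by the symptom's total
#' frequency across participants instead; `none` returns raw counts.
#'
#' @param census A `pcr_loop_census`.
#' @param records The records the census was computed on.
#' @param normalization One of `"per_endorsing_participant"`,
#'   `"per_frequency_sum"`, `"none"`.
#' @return Tibble with `id`, `raw`, `corrected`.
#' @export
symptom_involvement <- function(census, records,
                                normalization = c("per_endorsing_participant",
                                                  "per_frequency_sum",
                                                  "none")) {
  stopifnot(inherits(census, "pcr_loop_census"))
  normalization <- match.arg(normalization)
  raw <- census$involvement_raw
  n_endorse <- integer(40L)
  freq_tot <- numeric(40L)
  for (rec in records) {
    e <- endorsed_items(rec)
    n_endorse[e] <- n_endorse[e] + 1L
    fobs <- !is.na(rec$frequencies)
    freq_tot[fobs] <- freq_tot[fobs] + rec$frequencies[fobs]
  }
  corrected <- switch(
    normalization,
    per_endorsing_participant = ifelse(n_endorse > 0, raw / n_endorse, 0),
    per_frequency_sum = ifelse(freq_tot > 0, raw / freq_tot, 0),
    none = as.numeric(raw)
  )
  tibble(id = 1:40, raw = raw, corrected = corrected)
}

# partial Pearson correlation of x and y given a control matrix Z, via
# residualization
partial_pearson <- function(x, y, Z) {
  rx <- resid(lm(x ~ Z))
  ry <- resid(lm(y ~ Z))
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Association between feedback-loop count and symptom burden
#'
#' Spearman correlation of per-participant loop count with the symptom
#' frequency sum score, plus partial Spearman correlations (partial Pearson
#' on mid-rank-transformed variables) controlling for (1) the number of
#' endorsed symptoms and (2) additionally the number of PCR ratings. The
#' PCR-count control is the number of present ratings by default, or the
#' number of supra-threshold edges with `pcr_control = "edges"`. Two-tailed
#' p-values use the t approximation with df = n - 2 - (number of controls).
#'
#' @param census A `pcr_loop_census`.
#' @param records The records the census was computed on.
#' @param freq_items Item ids entering the frequency sum (default all 40).
#' @param pcr_control `"present"` or `"edges"`.
#' @return Tibble with one row per analysis (`unpartialled`,
#'   `partial_symptoms`, `partial_symptoms_pcr`): `rho`, `p`, `df`,
#'   `defined`.
#' @export
loop_burden_association <- function(census, records, freq_items = 1:40,
                                    pcr_control = c("present", "edges")) {
  stopifnot(inherits(census, "pcr_loop_census"))
  pcr_control <- match.arg(pcr_control)
  pt <- census$participants
  n <- nrow(pt)
  if (n < 10L) stop("need >= 10 participants")
  burden <- vapply(records[pt$participant_id], frequency_sum_score,
                   numeric(1), items = freq_items)
  loops <- pt$n_loops
  n_pcr <- if (pcr_control == "present") pt$n_pcr_present else pt$n_edges
  undefined_row <- function(label) {
    tibble(analysis = label, rho = NA_real_, p = NA_real_,
           df = NA_integer_, defined = FALSE)
  }
  if (sd(loops) == 0 || sd(burden) == 0) {
    return(rbind(undefined_row("unpartialled"),
                 undefined_row("partial_symptoms"),
                 undefined_row("partial_symptoms_pcr")))
  }
  ct <- suppressWarnings(
    cor.test(loops, burden, method = "spearman", exact = FALSE)
  )
  rows <- tibble(analysis = "unpartialled", rho = unname(ct$estimate),
                 p = ct$p.value, df = n - 2L, defined = TRUE)
  rl <- rank(loops); rb <- rank(burden)
  partial_row <- function(label, Z) {
    r <- partial_pearson(rl, rb, Z)
    k <- ncol(Z)
    if (is.na(r)) return(undefined_row(label))
    dfree <- n - 2L - k
    tstat <- r * sqrt(dfree / (1 - r^2))
    tibble(analysis = label, rho = r, p = 2 * pt(-abs(tstat), dfree),
           df = dfree, defined = TRUE)
  }
  rows <- rbind(
    rows,
    partial_row("partial_symptoms", cbind(rank(pt$n_symptoms))),
    partial_row("partial_symptoms_pcr",
                cbind(rank(pt$n_symptoms), rank(n_pcr)))
  )
  rows
}
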