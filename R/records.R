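# Missingness codes for frequency and PCR slots. A PCR slot for an ordered
# pair (i, j), i != j, is exactly one of: present, by_design (never asked
# because an endpoint was not endorsed), by_intention (asked but skipped).
STATUS_ABSENT <- 0L       # item never administered / not in file (frequency only)
STATUS_PRESENT <- 1L
STATUS_BY_DESIGN <- 2L
STATUS_BY_INTENTION <- 3L

status_label <- function(code) {
  c("absent", "present", "by_design", "by_intention")[code + 1L]
}

#' Construct a participant record
#'
#' A participant record holds one respondent's past-month symptom-frequency
#' ratings (ordinal 0-7) and their sparse directed PCR ratings (ordinal 0-10)
#' over the 40-item instrument, with typed missingness. PCR slots exist for
#' every ordered pair of distinct items; a slot is `present` (rated),
#' `by_design` (never asked: an endpoint's frequency is 0 or missing) or
#' `by_intention` (asked but skipped).
#'
#' @param participant_id Character scalar.
#' @param frequencies Integer vector of length 40 (values 0-7, `NA` =
#'   missing), or a named/partial vector indexed by item id; items not given
#'   are marked absent-from-file.
#' @param freq_status Optional integer status vector (internal use); derived
#'   from `frequencies` when `NULL`.
#' @param pcr Optional data frame with columns `cause_id`, `effect_id`,
#'   `value` (`NA` value = skipped by intention). Slots not listed are typed
#'   automatically: `by_design` where ineligible, `by_intention` where
#'   eligible but unrated.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, frequencies, freq_status = NULL,
                               pcr = NULL) {
  if (!is.character(participant_id) || length(participant_id) != 1L) {
    stop("participant_id must be a single character string")
  }
  freq <- rep(NA_integer_, 40L)
  if (!is.null(names(frequencies))) {
    ids <- as.integer(names(frequencies))
    if (any(is.na(ids)) || !all(ids %in% 1:40)) stop("bad item ids in frequencies")
    freq[ids] <- as.integer(frequencies)
    given <- ids
  } else if (length(frequencies) == 40L) {
    freq <- as.integer(frequencies)
    given <- 1:40
  } else {
    stop("frequencies must be length 40 or a named vector of item ids")
  }
  ok <- is.na(freq) | (freq >= 0L & freq <= 7L)
  if (!all(ok)) {
    stop("frequency outside 0-7 for item(s) ",
         paste(which(!ok), collapse = ", "))
  }
  if (is.null(freq_status)) {
    freq_status <- rep(STATUS_ABSENT, 40L)
    freq_status[given] <- ifelse(is.na(freq[given]),
                                 STATUS_BY_INTENTION, STATUS_PRESENT)
  }
  rec <- structure(
    list(
      participant_id = participant_id,
      frequencies = freq,
      freq_status = as.integer(freq_status),
      pcr = matrix(NA_real_, 40L, 40L),
      pcr_status = matrix(NA_integer_, 40L, 40L)
    ),
    class = "participant_record"
  )
  rec <- init_pcr_slots(rec)
  if (!is.null(pcr) && nrow(pcr) > 0) {
    for (r in seq_len(nrow(pcr))) {
      rec <- set_pcr(rec, as.integer(pcr$cause_id[r]),
                     as.integer(pcr$effect_id[r]), pcr$value[r])
    }
  }
  rec
}

# type every off-diagonal PCR slot: by_design where ineligible, by_intention
# where eligible but not (yet) rated
init_pcr_slots <- function(rec) {
  endorsed <- endorsed_items(rec)
  st <- matrix(STATUS_BY_DESIGN, 40L, 40L)
  if (length(endorsed) >= 2L) {
    st[endorsed, endorsed] <- STATUS_BY_INTENTION
  }
  diag(st) <- NA_integer_
  rec$pcr_status <- st
  rec$pcr <- matrix(NA_real_, 40L, 40L)
  rec
}

set_pcr <- function(rec, cause_id, effect_id, value) {
  if (cause_id == effect_id) stop("self-pairs have no PCR slot")
  if (is.na(rec$pcr_status[cause_id, effect_id]) ||
      rec$pcr_status[cause_id, effect_id] == STATUS_BY_DESIGN) {
    if (!is.na(value)) {
      stop("PCR value given for ineligible pair (", cause_id, ", ", effect_id,
           "): an endpoint's frequency is 0 or missing")
    }
    return(rec)  # blank entry for an ineligible pair: stays by_design
  }
  if (is.na(value)) {
    rec$pcr_status[cause_id, effect_id] <- STATUS_BY_INTENTION
    rec$pcr[cause_id, effect_id] <- NA_real_
  } else {
    if (value < 0 || value > 10) {
      stop("PCR value outside 0-10 for pair (", cause_id, ", ", effect_id, ")")
    }
    rec$pcr_status[cause_id, effect_id] <- STATUS_PRESENT
    rec$pcr[cause_id, effect_id] <- as.numeric(value)
  }
  rec
}

#' Items endorsed at least 'Once in the past month'
#'
#' @param record A `participant_record`.
#' @return Integer vector of item ids with observed frequency >= 1.
#' @export
endorsed_items <- function(record) {
  which(!is.na(record$frequencies) & record$frequencies >= 1L)
}

#' Ordered symptom pairs eligible for a causal-association question
#'
#' A pair (i, j) is eligible when both items were endorsed at least once in
#' the past month; each unordered pairing yields both permutations. Returned
#' in lexicographic (i, j) order.
#'
#' @param record A `participant_record`.
#' @return Two-column integer matrix (`cause_id`, `effect_id`); zero rows if
#'   fewer than two items endorsed.
#' @export
eligible_pairs <- function(record) {
  e <- endorsed_items(record)
  if (length(e) < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("cause_id", "effect_id"))))
  }
  grid <- expand.grid(effect_id = e, cause_id = e)[, 2:1]
  grid <- grid[grid$cause_id != grid$effect_id, ]
  grid <- grid[order(grid$cause_id, grid$effect_id), ]
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, c("cause_id", "effect_id"))
  m
}

#' Validate a participant record's internal consistency
#'
#' Checks the instrument's adaptive-questioning semantics: every eligible
#' ordered pair has a present or by_intention slot, no present PCR value
#' exists for an ineligible pair, and all values are in range.
#'
#' @param record A `participant_record`.
#' @return The record, invisibly; errors on violation.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "participant_record"))
  f <- record$frequencies
  if (!all(is.na(f) | (f >= 0L & f <= 7L))) stop("frequency outside 0-7")
  el <- eligible_pairs(record)
  st <- record$pcr_status
  if (nrow(el) > 0) {
    slot_st <- st[el]
    if (any(is.na(slot_st)) || any(slot_st == STATUS_BY_DESIGN)) {
      stop("eligible pair typed by_design")
    }
  }
  present <- which(st == STATUS_PRESENT, arr.ind = TRUE)
  if (nrow(present) > 0) {
    bad <- !(present[, 1] %in% endorsed_items(record)) |
      !(present[, 2] %in% endorsed_items(record))
    if (any(bad)) stop("present PCR value for ineligible pair")
    v <- record$pcr[present]
    if (any(is.na(v) | v < 0 | v > 10)) stop("present PCR slot without valid value")
  }
  n_slots <- sum(st %in% c(STATUS_PRESENT, STATUS_BY_INTENTION), na.rm = TRUE)
  k <- length(endorsed_items(record))
  if (n_slots != k * (k - 1L)) {
    stop("expected ", k * (k - 1L), " PCR slots, found ", n_slots)
  }
  invisible(record)
}

#' Aggregate a participant's frequency ratings over a named item subset
#'
#' Items rated 0 contribute 0; missing items are dropped (available-case).
#' Returns `NA` when no subset item has an observed rating.
#'
#' @param record A `participant_record`.
#' @param subset Subset name defined in the catalog (e.g. `"ANX"`).
#' @param catalog A `symptom_catalog`.
#' @param mode `"mean"` (default; robust to skipped items) or `"sum"`.
#' @return Numeric score or `NA`.
#' @export
subset_frequency_score <- function(record, subset, catalog = default_catalog(),
                                   mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  ids <- catalog_subset(catalog, subset)
  vals <- record$frequencies[ids]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (mode == "mean") mean(vals) else sum(vals)
}

#' Total symptom-frequency sum score
#'
#' The symptom-burden measure: available-case sum of frequency ratings over
#' the given item set (default all 40 items).
#'
#' @param record A `participant_record`.
#' @param items Item ids to include.
#' @return Numeric sum (0 if nothing observed).
#' @export
frequency_sum_score <- function(record, items = 1:40) {
  sum(record$frequencies[items], na.rm = TRUE)
}

#' Count of PCR slots with a present rating
#' @param record A `participant_record`.
#' @return Integer count.
#' @export
n_pcr_present <- function(record) {
  sum(record$pcr_status == STATUS_PRESENT, na.rm = TRUE)
}

#' @export
print.participant_record <- function(x, ...) {
  k <- length(endorsed_items(x))
  cat("<participant_record>", x$participant_id, "-", k, "endorsed symptoms,",
      n_pcr_present(x), "present PCR ratings\n")
  invisible(x)
}
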