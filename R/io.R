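# Long-format CSV readers/writers for PCR-scaling data.
# Dialect: UTF-8, header row required; by_intention encoded as an empty cell;
# by_design slots are never serialized (they are reconstructed from the
# frequency table's eligibility rule on read).

#' Read a long-format symptom-frequency table
#'
#' Expects columns `participant_id`, `symptom_id`, `frequency`; an empty
#' `frequency` cell means the question was skipped (missing by intention).
#' Items with no row at all are marked absent-from-file.
#'
#' @param path CSV path.
#' @param catalog A `symptom_catalog` used to validate item ids.
#' @return Named list of `participant_record` (frequencies only), keyed by
#'   participant id, in first-appearance order.
#' @export
load_frequency_table <- function(path, catalog = default_catalog()) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("participant_id", "symptom_id", "frequency")
  if (!all(required %in% names(df))) {
    stop("frequency table must have columns: ", paste(required, collapse = ", "))
  }
  sid <- suppressWarnings(as.integer(df$symptom_id))
  bad <- which(is.na(sid) & nzchar(df$symptom_id))
  bad <- union(bad, which(is.na(sid)))
  if (length(bad) > 0) {
    stop("malformed symptom_id at data row ", bad[1])
  }
  unknown <- which(!sid %in% catalog$items$id)
  if (length(unknown) > 0) {
    stop("unknown symptom id ", sid[unknown[1]], " at data row ", unknown[1])
  }
  fr_chr <- trimws(df$frequency)
  fr <- suppressWarnings(as.integer(fr_chr))
  malformed <- which(nzchar(fr_chr) & is.na(fr))
  if (length(malformed) > 0) {
    stop("malformed frequency '", fr_chr[malformed[1]], "' at data row ",
         malformed[1])
  }
  out_of_range <- which(!is.na(fr) & (fr < 0L | fr > 7L))
  if (length(out_of_range) > 0) {
    stop("frequency ", fr[out_of_range[1]], " outside 0-7 at data row ",
         out_of_range[1])
  }
  dup <- duplicated(paste(df$participant_id, sid))
  if (any(dup)) {
    stop("duplicate (participant, symptom) entry at data row ", which(dup)[1])
  }
  records <- list()
  for (pid in unique(df$participant_id)) {
    rows <- df$participant_id == pid
    freqs <- setNames(fr[rows], sid[rows])
    records[[pid]] <- participant_record(pid, freqs)
  }
  records
}

#' Read a long-format PCR table into frequency records
#'
#' Expects columns `participant_id`, `cause_id`, `effect_id`, `pcr`; an empty
#' `pcr` cell means skipped by intention. Eligible pairs absent from the file
#' become by_intention; ineligible pairs are typed by_design. A present value
#' for an ineligible pair signals corrupted input and raises an error.
#'
#' @param path CSV path.
#' @param records Named list of `participant_record` from
#'   [load_frequency_table()].
#' @return The records with PCR slots populated and validated.
#' @export
load_pcr_table <- function(path, records) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("participant_id", "cause_id", "effect_id", "pcr")
  if (!all(required %in% names(df))) {
    stop("pcr table must have columns: ", paste(required, collapse = ", "))
  }
  ci <- suppressWarnings(as.integer(df$cause_id))
  ei <- suppressWarnings(as.integer(df$effect_id))
  if (any(is.na(ci)) || any(is.na(ei))) {
    stop("malformed cause/effect id at data row ",
         which(is.na(ci) | is.na(ei))[1])
  }
  v_chr <- trimws(df$pcr)
  v <- suppressWarnings(as.numeric(v_chr))
  malformed <- which(nzchar(v_chr) & is.na(v))
  if (length(malformed) > 0) {
    stop("malformed pcr value '", v_chr[malformed[1]], "' at data row ",
         malformed[1])
  }
  out_of_range <- which(!is.na(v) & (v < 0 | v > 10))
  if (length(out_of_range) > 0) {
    stop("pcr value outside 0-10 at data row ", out_of_range[1])
  }
  dup <- duplicated(paste(df$participant_id, ci, ei))
  if (any(dup)) stop("duplicate PCR entry at data row ", which(dup)[1])
  unknown <- which(!df$participant_id %in% names(records))
  if (length(unknown) > 0) {
    stop("pcr table references unknown participant '",
         df$participant_id[unknown[1]], "' at data row ", unknown[1])
  }
  for (r in seq_len(nrow(df))) {
    pid <- df$participant_id[r]
    records[[pid]] <- set_pcr(records[[pid]], ci[r], ei[r],
                              if (nzchar(v_chr[r])) v[r] else NA_real_)
  }
  for (pid in names(records)) validate_record(records[[pid]])
  records
}

#' Write records back to the long CSV dialect
#'
#' `write_frequency_table` writes one row per administered item (empty cell
#' for by_intention); `write_pcr_table` writes one row per eligible ordered
#' pair (empty cell for by_intention) and never serializes by_design slots.
#' A write-then-read round trip reproduces the records field-for-field.
#'
#' @param records Named list of `participant_record`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_frequency_table <- function(records, path) {
  rows <- lapply(records, function(rec) {
    admin <- which(rec$freq_status %in% c(STATUS_PRESENT, STATUS_BY_INTENTION))
    if (length(admin) == 0L) return(NULL)
    data.frame(
      participant_id = rec$participant_id,
      symptom_id = admin,
      frequency = ifelse(is.na(rec$frequencies[admin]), "",
                         as.character(rec$frequencies[admin])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), symptom_id = integer(0),
                      frequency = character(0))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
write_pcr_table <- function(records, path) {
  rows <- lapply(records, function(rec) {
    ask <- matrix(rec$pcr_status %in% c(STATUS_PRESENT, STATUS_BY_INTENTION),
                  40L, 40L)
    slots <- which(ask, arr.ind = TRUE)
    if (nrow(slots) == 0L) return(NULL)
    ord <- order(slots[, 1], slots[, 2])
    slots <- slots[ord, , drop = FALSE]
    vals <- rec$pcr[slots]
    data.frame(
      participant_id = rec$participant_id,
      cause_id = slots[, 1],
      effect_id = slots[, 2],
      pcr = ifelse(is.na(vals), "", as.character(vals)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), cause_id = integer(0),
                      effect_id = integer(0), pcr = character(0))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
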