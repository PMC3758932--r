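#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor cor.test lm pf pt qnorm quantile rnorm runif sd setNames t.test p.adjust complete.cases coef vcov resid var median
#' @importFrom utils read.csv write.csv head
NULL

# valid category codes for instrument items
PCR_CATEGORIES <- c("ANX", "PTSD", "MDD", "DISSOC", "OTHER", "IMPAIRMENT", "PTSD&MDD")

#' Construct a symptom catalog
#'
#' A symptom catalog describes the 40-item PCR instrument: the ordered item
#' list (id, label, abbreviation, category) plus named item subsets used for
#' composite scores. Optional per-item columns `freq_mean`, `freq_sd` and
#' `n_rated` carry reference endorsement statistics used to calibrate the
#' synthetic-data generator.
#'
#' @param items A data frame with columns `id` (integer 1-40), `label`,
#'   `abbreviation`, `category`, and optionally `freq_mean`, `freq_sd`,
#'   `n_rated`.
#' @param subsets Named list of integer item-id vectors.
#' @return An object of class `symptom_catalog`.
#' @export
symptom_catalog <- function(items, subsets = list()) {
  items <- as_tibble(items)
  required <- c("id", "label", "abbreviation", "category")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    stop("catalog items lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  items$id <- as.integer(items$id)
  if (nrow(items) != 40L) stop("a symptom catalog must have exactly 40 items")
  if (!identical(sort(items$id), 1:40)) {
    stop("item ids must be the unique integers 1..40")
  }
  if (anyDuplicated(items$abbreviation)) stop("item abbreviations must be unique")
  if (any(!nzchar(items$label)) || any(!nzchar(items$abbreviation))) {
    stop("item labels and abbreviations must be non-empty")
  }
  bad_cat <- setdiff(unique(items$category), PCR_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown item category: ", paste(bad_cat, collapse = ", "))
  }
  items <- items[order(items$id), ]
  for (nm in names(subsets)) {
    ids <- as.integer(subsets[[nm]])
    if (anyDuplicated(ids)) stop("subset '", nm, "' contains duplicate ids")
    if (!all(ids %in% items$id)) stop("subset '", nm, "' references unknown ids")
    subsets[[nm]] <- ids
  }
  structure(list(items = items, subsets = subsets), class = "symptom_catalog")
}

#' The built-in 40-item PCR symptom catalog
#'
#' The instrument covers all major depressive episode symptoms, DSM-IV PTSD
#' symptoms (minus traumatic amnesia), four anxiety-disorder items, a
#' guilt/shame item, dissociation screens, and impairment items. The named
#' subsets are the composites used throughout the analyses:
#' ANX = items 1-4, DEP = items 12, 13, 18, 24, 27-30, 32, 33,
#' REEXP = items 5-9 (DSM-IV PTSD criterion-B reexperiencing).
#'
#' `freq_mean` / `freq_sd` are past-month frequency statistics (0-7 scale) and
#' `n_rated` the number of respondents contributing a paired cause/effect
#' score, from a reference young-adult survey sample (n = 288). They are used
#' only as calibration defaults for [simulation_config()].
#'
#' @return A `symptom_catalog`.
#' @export
default_catalog <- function() {
  items <- tibble(
    id = 1:40,
    label = c(
      "Panic attacks",
      "Anxious worrying",
      "Social anxiety",
      "Agoraphobic behavior",
      "Intrusive memories of a traumatic event",
      "Dreams/nightmares about a traumatic event",
      "Emotional upset at reminder of a traumatic event",
      "Physiological reaction at reminder of a traumatic event",
      "Flashbacks of a traumatic event",
      "Avoidance of thoughts/feelings about a traumatic event",
      "Avoidance of reminders of a traumatic event",
      "Loss of interest",
      "Depressed mood",
      "Feeling distant or cut off from others",
      "Emotional numbness",
      "Sense of foreshortened future or loss of core life goals",
      "Irritability/anger",
      "Thinking/concentration problems",
      "Hypervigilance",
      "Strong startle reactions",
      "Derealization",
      "Depersonalization",
      "Identity confusion",
      "Feeling worthless",
      "Guilt and/or shame",
      "Self-harming behavior",
      "Suicidal thinking/behavior",
      "Psychomotor agitation",
      "Psychomotor slowing",
      "Energy loss/fatigue",
      "Hypomania",
      "Sleeping problems",
      "Eating problems",
      "Sexual problems",
      "Pain problems",
      "Interpersonal problems",
      "Work and/or school problems",
      "Alcohol/substance abuse problems",
      "Lost time",
      "Hearing voices inside your head"
    ),
    abbreviation = c(
      "PANC", "WRRY", "SCAX", "AGOR", "MEMT", "DRM", "EMOT", "PHYS", "FLSH",
      "AVTH", "AVAC", "LSIN", "DPRM", "DIST", "NUMB", "FRZN", "IRRI", "DCNC",
      "HVGL", "STRT", "DREA", "DPRS", "IDCF", "WRTL", "SHME", "SHRM", "SUIC",
      "AGIT", "SLOW", "FTIG", "HPOM", "SLP", "EAT", "SEX", "PAIN", "SCRL",
      "WRK", "ALC", "TIME", "VOIC"
    ),
    category = c(
      "ANX", "ANX", "ANX", "ANX", "PTSD", "PTSD", "PTSD", "PTSD", "PTSD",
      "PTSD", "PTSD", "PTSD&MDD", "MDD", "PTSD", "PTSD", "PTSD", "PTSD",
      "PTSD&MDD", "PTSD", "PTSD", "DISSOC", "DISSOC", "DISSOC", "MDD",
      "OTHER", "OTHER", "MDD", "MDD", "MDD", "MDD", "OTHER", "PTSD&MDD",
      "MDD", "OTHER", "OTHER", "IMPAIRMENT", "IMPAIRMENT", "OTHER",
      "DISSOC", "DISSOC"
    ),
    freq_mean = c(
      0.85, 1.42, 0.79, 0.37, 0.59, 0.33, 0.59, 0.43, 0.26, 0.41, 0.38, 0.89,
      1.24, 1.22, 0.67, 0.93, 1.05, 1.61, 0.85, 0.85, 0.50, 0.47, 0.59, 0.80,
      1.11, 0.16, 0.28, 0.79, 0.34, 1.35, 0.24, 1.52, 1.23, 0.37, 0.64, 1.00,
      0.96, 0.63, 0.37, 0.11
    ),
    freq_sd = c(
      1.20, 1.61, 1.32, 1.08, 1.19, 0.82, 1.18, 1.06, 0.84, 1.02, 1.13, 1.43,
      1.47, 1.58, 1.24, 1.43, 1.35, 1.75, 1.44, 1.42, 1.10, 1.05, 1.20, 1.45,
      1.54, 0.64, 0.80, 1.41, 0.89, 1.71, 0.60, 1.80, 1.68, 1.01, 1.31, 1.44,
      1.53, 1.33, 0.89, 0.67
    ),
    n_rated = c(
      131L, 174L, 111L, 45L, 84L, 60L, 82L, 61L, 38L, 63L, 47L, 124L, 178L,
      157L, 92L, 121L, 144L, 185L, 111L, 112L, 75L, 72L, 83L, 104L, 139L,
      26L, 38L, 103L, 57L, 161L, 47L, 154L, 137L, 50L, 81L, 129L, 114L, 70L,
      59L, 12L
    )
  )
  symptom_catalog(
    items,
    subsets = list(
      ANX = 1:4,
      DEP = c(12L, 13L, 18L, 24L, 27:30, 32L, 33L),
      REEXP = 5:9
    )
  )
}

#' Look up a subset's item ids
#' @param catalog A `symptom_catalog`.
#' @param name Subset name.
#' @return Integer vector of item ids.
#' @export
catalog_subset <- function(catalog, name) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  if (!name %in% names(catalog$subsets)) {
    stop("unknown subset '", name, "'; available: ",
         paste(names(catalog$subsets), collapse = ", "))
  }
  catalog$subsets[[name]]
}

#' Write / read a catalog as JSON
#'
#' @param catalog A `symptom_catalog`.
#' @param path File path.
#' @return `read_catalog` returns a `symptom_catalog`; `write_catalog` its
#'   path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  out <- list(
    items = catalog$items,
    subsets = catalog$subsets
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  subsets <- lapply(raw$subsets, as.integer)
  symptom_catalog(raw$items, subsets = subsets)
}

#' @export
print.symptom_catalog <- function(x, ...) {
  cat("<symptom_catalog> 40 items;",
      "subsets:", paste(names(x$subsets), collapse = ", "), "\n")
  print(head(x$items, 5))
  cat("...\n")
  invisible(x)
}
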