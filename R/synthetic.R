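# Synthetic PCR-scaling populations with a known ground-truth causal
# structure. The study design this emulates: 40 symptoms rated for past-month
# frequency (0-7, zero-inflated), then a directed 0-10 causal-association
# rating for every ordered pair of endorsed symptoms, with ~2% of frequency
# and <1% of PCR answers skipped by the respondent.

#' Ground truth for the synthetic-population generator
#'
#' @param causal_weights 40x40 non-negative matrix `W` (zero diagonal);
#'   `W[i, j]` is the true strength with which symptom i drives symptom j.
#' @param planted_loops List of integer id vectors; each is a directed simple
#'   cycle whose edges are (additionally) set to `loop_weight`.
#' @param base_rates Length-40 vector of endorsement probabilities in `[0,1]`.
#' @param noise Single rating-noise scale: the SD of Gaussian noise on the
#'   0-10 PCR scale; activations (unit scale) use `noise / 10`.
#' @param pcr_fidelity Non-negative slope linking true weight to the expected
#'   PCR rating: `E[PCR(i,j)] = pcr_fidelity * W[i, j]` before clipping.
#' @param activation_gain Coupling scale of the structural activation pass.
#' @param loop_weight Weight assigned to planted loop edges.
#' @return An object of class `pcr_ground_truth`.
#' @export
ground_truth <- function(causal_weights, planted_loops = list(),
                         base_rates = rep(0.3, 40), noise = 2,
                         pcr_fidelity = 7, activation_gain = 0.3,
                         loop_weight = 0.85) {
  W <- as.matrix(causal_weights)
  if (!all(dim(W) == c(40L, 40L))) stop("causal_weights must be 40x40")
  if (any(W < 0)) stop("causal weights must be non-negative")
  if (any(diag(W) != 0)) stop("causal_weights must have a zero diagonal")
  for (loop in planted_loops) {
    loop <- as.integer(loop)
    if (length(loop) < 2L || anyDuplicated(loop) || !all(loop %in% 1:40)) {
      stop("each planted loop must be >=2 distinct ids in 1..40")
    }
    nxt <- c(loop[-1], loop[1])
    W[cbind(loop, nxt)] <- loop_weight
  }
  if (length(base_rates) != 40L || any(base_rates < 0 | base_rates > 1)) {
    stop("base_rates must be 40 probabilities in [0,1]")
  }
  if (pcr_fidelity < 0) stop("pcr_fidelity must be >= 0")
  if (noise < 0) stop("noise must be >= 0")
  structure(
    list(causal_weights = W, planted_loops = planted_loops,
         base_rates = as.numeric(base_rates), noise = noise,
         pcr_fidelity = pcr_fidelity, activation_gain = activation_gain),
    class = "pcr_ground_truth"
  )
}

#' Default ground truth mirroring the instrument's reference sample
#'
#' Base endorsement rates are calibrated from the catalog's reference
#' statistics (`n_rated / 288`). The weight matrix is sparse: a weak
#' within-category background (0.15), a handful of structural cross-category
#' links (0.5) along the worry -> sleep -> fatigue and
#' reexperiencing/shame -> depressed-mood axes, and planted feedback loops
#' (0.85) among reexperiencing, worry, shame and depressed mood so the
#' population contains true causal cycles.
#'
#' @param catalog A `symptom_catalog` supplying categories and reference
#'   endorsement counts.
#' @param ... Overrides passed on to [ground_truth()].
#' @return A `pcr_ground_truth`.
#' @export
default_ground_truth <- function(catalog = default_catalog(), ...) {
  W <- matrix(0, 40L, 40L)
  cats <- catalog$items$category
  for (cc in unique(cats)) {
    ids <- which(cats == cc)
    W[ids, ids] <- 0.15
  }
  diag(W) <- 0
  # structural directed links (cause row -> effect column):
  # worry->sleep, sleep->fatigue, worry->concentration,
  # memories->depressed mood, shame->memories, shame->depressed mood,
  # memories->emotional upset, anxiety items->depressed mood
  links <- rbind(
    c(2L, 32L), c(32L, 30L), c(2L, 18L), c(5L, 13L), c(25L, 5L),
    c(25L, 13L), c(5L, 7L), c(1L, 13L), c(3L, 13L)
  )
  W[links] <- 0.5
  defaults <- list(
    causal_weights = W,
    planted_loops = list(c(5L, 13L), c(2L, 13L), c(7L, 5L), c(5L, 25L, 13L)),
    base_rates = pmin(pmax(catalog$items$n_rated / 288, 0.02), 0.98)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(ground_truth, args)
}

#' Simulation configuration
#'
#' @param n_participants Number of respondents (default 288, the reference
#'   sample size).
#' @param seed Mandatory RNG seed.
#' @param truth A `pcr_ground_truth`.
#' @param freq_missing_rate Probability a frequency answer is skipped
#'   (default 0.02).
#' @param pcr_missing_rate Probability a PCR answer is skipped
#'   (default 0.0075, i.e. under 1%).
#' @param n_iterations Structural-pass iteration count (fixed small number).
#' @return An object of class `pcr_simulation_config`.
#' @export
simulation_config <- function(n_participants = 288L, seed,
                              truth = default_ground_truth(),
                              freq_missing_rate = 0.02,
                              pcr_missing_rate = 0.0075,
                              n_iterations = 3L) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_participants < 1L) stop("n_participants must be >= 1")
  rates <- c(freq_missing_rate, pcr_missing_rate)
  if (any(rates < 0 | rates > 1)) stop("missing rates must be in [0,1]")
  stopifnot(inherits(truth, "pcr_ground_truth"))
  structure(
    list(n_participants = as.integer(n_participants), seed = as.integer(seed),
         truth = truth, freq_missing_rate = freq_missing_rate,
         pcr_missing_rate = pcr_missing_rate,
         n_iterations = as.integer(n_iterations)),
    class = "pcr_simulation_config"
  )
}

# run expr with a locally seeded RNG, restoring global RNG state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a PCR-scaling population with known ground truth
#'
#' Deterministic given the config (which carries the seed). Per participant:
#' (1) latent activations follow an iterated clipped-linear structural pass
#' `a <- clip(base + gain * W'a + eps, 0, 1)` (noise drawn once, so planted
#' feedback loops amplify the activation of their member symptoms);
#' (2) activation maps to ordinal frequency 0-7 by eight equally spaced
#' thresholds (activation below 1/8 gives frequency 0, the zero-inflation
#' mass); (3) every eligible ordered pair gets
#' `PCR = round(clip(pcr_fidelity * W[i,j] + noise, 0, 10))`; ineligible
#' pairs are missing by design; (4) by-intention missingness is injected at
#' the configured rates. `base` is calibrated per symptom so that, absent
#' network effects, the endorsement probability equals `base_rates`.
#'
#' @param config A `pcr_simulation_config`.
#' @return List with `records` (named list of `participant_record`) and
#'   `truth` (the `pcr_ground_truth` actually used).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "pcr_simulation_config"))
  truth <- config$truth
  W <- truth$causal_weights
  sigma_a <- truth$noise / 10
  t1 <- 1 / 8  # first ordinal threshold on the unit activation scale
  base <- t1 + sigma_a * qnorm(truth$base_rates)
  if (sigma_a == 0) base <- ifelse(truth$base_rates >= 0.5, t1, t1 - 1)
  tW <- t(W)  # activation of j accumulates W[i,j] * a[i]
  records <- with_local_seed(config$seed, {
    out <- vector("list", config$n_participants)
    for (p in seq_len(config$n_participants)) {
      eps <- rnorm(40L, 0, sigma_a)
      a <- pmin(pmax(base + eps, 0), 1)
      for (it in seq_len(config$n_iterations)) {
        a <- pmin(pmax(base + truth$activation_gain * drop(tW %*% a) + eps, 0), 1)
      }
      freq <- pmin(floor(a * 8), 7)
      freq <- as.integer(freq)
      skip_f <- runif(40L) < config$freq_missing_rate
      freq_obs <- ifelse(skip_f, NA_integer_, freq)
      status <- ifelse(skip_f, STATUS_BY_INTENTION, STATUS_PRESENT)
      rec <- participant_record(sprintf("P%04d", p), freq_obs,
                                freq_status = status)
      pairs <- eligible_pairs(rec)
      if (nrow(pairs) > 0) {
        mu <- truth$pcr_fidelity * W[pairs]
        val <- round(pmin(pmax(mu + rnorm(nrow(pairs), 0, truth$noise), 0), 10))
        skip_p <- runif(nrow(pairs)) < config$pcr_missing_rate
        for (r in seq_len(nrow(pairs))) {
          rec <- set_pcr(rec, pairs[r, 1], pairs[r, 2],
                         if (skip_p[r]) NA_real_ else val[r])
        }
      }
      out[[p]] <- rec
    }
    names(out) <- vapply(out, `[[`, character(1), "participant_id")
    out
  })
  list(records = records, truth = truth)
}

#' Expected feedback loops implied by a ground truth
#'
#' Thresholds the true weight matrix at `cutoff` and enumerates its simple
#' directed cycles of length 2-4; this is the oracle for loop-recovery tests.
#'
#' @param truth A `pcr_ground_truth`.
#' @param cutoff Weight threshold (strictly greater-than).
#' @param max_len Maximum cycle length (default 4).
#' @return List of canonical integer cycles (see [enumerate_cycles()]).
#' @export
planted_loop_census <- function(truth, cutoff, max_len = 4L) {
  stopifnot(inherits(truth, "pcr_ground_truth"))
  adj <- truth$causal_weights > cutoff
  enumerate_cycles(adj, max_len = max_len)
}
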