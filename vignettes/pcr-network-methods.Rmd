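---
title: "Perceived causal relations: scoring, models, networks and feedback loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceived causal relations: scoring, models, networks and feedback loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrnet)
```

## The measurement problem

Clinical problems rarely occur alone, and people hold beliefs about which of
their problems cause which others. Perceived Causal Relations (PCR) scaling
measures those beliefs directly: a respondent first rates the past-month
frequency of each of 40 symptoms on an eight-point ordinal scale (0 = "not
at all" to 7 = "daily or almost daily for most of the day"); every symptom
endorsed at least once then enters pairwise follow-up questions of the form
"How much do you think your problems with X cause your problems with Y?",
rated 0--10, asked in **both directions** for every endorsed pair.

This adaptive design produces data with two distinct kinds of missingness,
and keeping them distinct is the core of the data model in `pcr_core`:

* **missing by design** -- a causal question never asked, because at least
  one endpoint was not endorsed in the past month;
* **missing by intention** -- a question presented but skipped by the
  respondent.

Both are treated as missing in every analysis (available-case analysis, no
imputation), but the typing is load-bearing for validation: a PCR value
recorded for a by-design slot can only be corrupted input, and a record
with `k` endorsed symptoms must expose exactly `k(k-1)` rated-or-skipped
slots. `validate_record()` enforces these invariants, and the CSV
readers/writers (`load_frequency_table()`, `load_pcr_table()`,
`write_*_table()`) round-trip them exactly: by-intention answers serialize
as empty cells, by-design slots are never serialized and are reconstructed
from the eligibility rule on read.

Subset composites use the instrument's standard index sets: ANX (items
1--4), DEP (items 12, 13, 18, 24, 27--30, 32, 33) and REEXP (items 5--9).
Subset *frequency* scores default to the **mean** of the available items
rather than their sum: with a handful of by-intention gaps a mean stays on
the 0--7 scale and comparable across respondents, while a sum would
conflate missingness with low burden. The 40-item symptom-burden measure
used in the loop analysis (`frequency_sum_score()`) is deliberately a sum,
which is the convention for total frequency scores; its item set is an
argument in case impairment items should be excluded.

## Cause-versus-effect scoring

For each symptom, the **mean causal association** score C is the average of
the present PCR ratings the symptom receives as the cause across all rated
partners, and the **mean effect association** score E its average as the
effect. `cause_effect_comparison()` contrasts C and E across participants
with a paired two-tailed t test, reports their correlation `r_EC`, and an
effect size computed from the t statistic:

d = |t| / sqrt(df + 1),

i.e. the standardized mean difference recovered from the t value and the
number of pairs. This convention reproduces the worked examples it is
checked against (t = 4.95 with df = 112 gives d = 0.47; t = 6.74 with
df = 195 gives 0.48; t = 3.78 with df = 137 gives 0.32). Alternative d
conventions exist for paired designs (some divide by sqrt(df), some
standardize by the difference SD); for rounded two-decimal reporting the
choice is immaterial in all checked cases but one should not mix
conventions, so the package exposes exactly this one
(`cohens_d_from_t()`).

Two degenerate situations are handled explicitly rather than numerically:
when every participant has C = E the paired t is defined as 0 with p = 1;
when the differences are constant but non-zero (zero variance, non-zero
mean) the contrast is flagged `defined = FALSE` instead of returning an
infinite statistic.

Family-wise control over the 40 per-symptom contrasts uses Holm's step-down
procedure (`holm_bonferroni()`, decisions identical to
`stats::p.adjust(method = "holm")`), which reports the plain Bonferroni
threshold `alpha/m` (0.00125 at alpha = 0.05, m = 40) and the *obtained*
threshold, the largest raw p-value still rejected -- a useful summary when
comparing against tabulated results. In the instrument-wide table
(`cause_effect_table()`), d is reported only for corrected-significant
contrasts; `d_raw` retains the rest.

## Regression designs

Three designs relate disorder-level frequency composites to PCR composites
(`subset_pcr_score()`, the within-participant mean of present ratings from
one item set to another). All of them are estimated by OLS with listwise
deletion per model, so each model's df reflects its own available cases.

**Moderation** (`fit_moderation()`): y on x, w and x·w with x and w
mean-centered before the product, so b1 and b2 are simple effects at the
means. The interaction's contribution is summarized by the increment in R²
with its F test on df (1, n-4), and probed by simple slopes at moderator
values (default ±1 SD) with delta-method standard errors. The
interaction-contrast effect size (`simple_slope_contrast_d()`) is

d = b3 (w_hi − w_lo) x_probe / sigma_residual,

the model-implied outcome difference between high- and low-moderator
respondents at a probe value of the predictor, **attributable to the
interaction term alone**, in residual-SD units. The moderator's main
effect is excluded on purpose: including b2 (w_hi − w_lo) would make the
"moderation effect size" non-zero even when b3 = 0, and the index is meant
to be zero exactly when there is nothing to moderate. It is linear in b3
by construction.

**Mediation** (`fit_mediation()`): a from m ~ x; b and the direct effect c'
from y ~ x + m; total effect c from y ~ x. In OLS with complete data
c = c' + ab exactly, and the test suite asserts that identity. Inference on
the indirect effect ab and on the ratio ab/c' uses a nonparametric
case-resampling **percentile** bootstrap (default 10,000 resamples), the
approach whose confidence limits the percentile-style reporting here
mirrors; bias-corrected variants are deliberately not the default. A
resample in which x or m collapses to zero variance is redrawn and counted
(`n_redrawn`). Two "proportion mediated" conventions are both reported --
ab/c and ab/(ab + c') -- because the two disagree whenever c' and ab have
opposite signs and summaries like "explains 14% of the total effect" do
not identify which was used.

**Moderated mediation** (`fit_moderated_mediation()`): the mediator model
m ~ x + w + x·w (first-stage moderator w) and outcome model
y ~ x + m + v + m·v (second-stage moderator v), all product terms on
mean-centered variables. The conditional indirect effect at (w0, v0) is
(a1 + a3 w0)(b1 + b3 v0), evaluated on a probe grid -- by default the
quartiles of each centered moderator, so the median is always a probe --
with percentile CIs computed from **one** shared set of bootstrap
resamples across all cells (grid cells are comparable because they see the
same resampling noise). A documented variant of the outcome model adds the
cross-moderator products w·v and m·w·v: a single coefficient for "the two
PCR moderators interact" is sometimes the quantity of interest, and it is
not identified in the standard two-equation parameterisation. The variant
is reported alongside (`$variant_wv`), never silently substituted.

Confidence levels default to 95%; 98.33% -- a Bonferroni-corrected 95%
across three model families, equivalently alpha = 0.05/3 = 0.017 -- is a
single argument away and is what `analysis/03_models.R` uses.

## The group symptom network

`build_mean_network()` averages present PCR(i, j) ratings over the
participants who endorsed (and rated) both symptoms, yielding a directed
weighted network over all 40 symptoms with mean frequency as a node
attribute. Thresholds of 3 and 4.5 (`threshold_network()`, strict `>` by
default) distinguish moderate from strong perceived links for display.

Three weighted centralities are computed. Outdegree and indegree are edge-
weight sums. Betweenness follows the shortest-path generalization for
weighted graphs in which an edge of weight w costs w^(-alpha) to traverse
(default alpha = 1, cost 1/weight: stronger causal links are shorter);
a node's score is the sum over ordered pairs (s, t) of the fraction of
minimal-cost s→t paths passing through it. Implementation is Brandes'
accumulation over Dijkstra trees, with fractional credit across co-minimal
paths (relative tolerance 1e-10 for cost ties), zero-weight edges excluded
as infinite-cost, and unreachable pairs contributing nothing. Scores are
raw pair counts; normalization by (n−1)(n−2) is an option. The test suite
pins this implementation to an exhaustive all-simple-paths oracle on small
random digraphs and to igraph's independent implementation on inverse
weights, and alpha is exposed because published analyses rarely state it.

Centrality extremity is judged against a permutation null
(`permutation_null()`): by default the multiset of observed mean edge
weights is randomly permuted over the **existing** edge positions (1,000
networks), preserving topology; `rewire_pairs` instead scatters the
weights over all 40·39 ordered pairs, for the reading in which the
permutation also randomizes structure. Per node and measure the 2.5th,
50th and 97.5th percentiles of the permuted centralities are reported and
a node is flagged when its observed value falls outside the central 95%
interval (strict inequalities, so a flat network in which permutation
changes nothing flags nobody). Permutation is without replacement -- a true
permutation null, not a resampling bootstrap -- because the quantity being
tested is the arrangement of the observed weights, not sampling error.

Layout for display is Fruchterman--Reingold (igraph), seeded and centered,
so strongly connected symptom clusters sit together reproducibly.

## Feedback loops

At the individual level, `participant_network()` keeps the PCR ratings
above 4.5 (strict `>`, read literally from "scores above 4.5"; the
operator is configurable) among endorsed symptoms, and
`enumerate_cycles()` lists all simple directed cycles of 2 to 4 distinct
symptoms -- perceived causal feedback loops. Enumeration is a bounded-depth
DFS anchored at each cycle's smallest node id, which yields every cycle
exactly once, already in canonical rotation, in deterministic
lexicographic order; with the length bound at 4 this is exact and fast
even on the complete 40-node digraph, where subsets-times-orientations
counting gives 41,340 cycles. Cycle length 2 is the minimum since the
instrument never asks self-cause questions.

`loop_census()` reports both possible semantics of a population loop
total -- (participant, loop) incidences and distinct pooled loop types --
because a headline count like "281,936 unique feedback loops" does not
identify which is meant. Per-symptom involvement divides incidence counts
by the number of participants endorsing the symptom (default), by the
symptom's total frequency, or not at all; the per-endorser correction is
the default because involvement opportunity scales with endorsement, and
the alternatives remain one argument away.

`loop_burden_association()` relates per-participant loop counts to the
40-item frequency sum score by Spearman's rho, then partials out (1) the
number of endorsed symptoms and (2) additionally the number of PCR
ratings, since both mechanically expand the space of possible loops. The
partial coefficient is the partial Pearson correlation on mid-rank
transformed variables -- the standard reading of "Spearman's rho,
partialling out" -- with two-tailed p from the t approximation on
df = n − 2 − k. The PCR-count control defaults to present ratings, with
supra-threshold edge count as the alternative. Zero variance in either
variable returns an explicit undefined marker.

## The synthetic population

No respondent-level data is distributed with the package, so
`simulate_population()` generates populations from a known
`ground_truth()`: a 40×40 non-negative weight matrix W (planted directed
loops included), per-symptom base endorsement rates, one noise scale, and
a fidelity slope linking true weight to expected rating.

Per participant:

1. latent activations follow an iterated clipped-linear structural pass,
   `a ← clip(base + gain · Wᵀa + ε, 0, 1)` for 3 iterations with ε drawn
   once per participant -- the minimal mechanism by which planted feedback
   loops amplify the activation, hence the frequency, of their member
   symptoms;
2. activation maps to ordinal frequency by eight equally spaced thresholds
   (below 1/8 → 0, providing the zero inflation); `base` is calibrated so
   that absent network effects the endorsement probability equals the
   configured base rate;
3. each eligible ordered pair receives
   `PCR = round(clip(fidelity · W[i,j] + N(0, noise), 0, 10))`;
   ineligible pairs are missing by design;
4. by-intention missingness is injected completely at random at 2%
   (frequency) and 0.75% (PCR), the rates the instrument showed in its
   reference sample.

Defaults are fixed once to emulate that reference sample: n = 288;
base rates taken from the catalog's per-item rated-pair counts
(`n_rated/288`); `noise = 2` on the 0--10 scale (matching typical rating
SDs of about 2, and `noise/10` on the unit activation scale);
`pcr_fidelity = 7`, so planted loop edges (weight 0.85) rate around 6 --
above the 4.5 loop threshold -- while structural links (0.5) rate around
3.5 and the weak within-category background (0.15) around 1. The
`activation_gain` (0.3) keeps the clipped pass away from saturation with
this sparse W. The generator is deterministic given its mandatory seed and
leaves the caller's RNG stream untouched.

What the generator does **not** emulate: ordinal measurement error
structured by item content, respondent-level response styles (acquiescence,
scale compression), informative skipping (its missingness is MCAR), and
any true moderation or mediation among composites -- PCR ratings are noisy
readouts of W, not causal players. Recovery tests on synthetic data
therefore validate the estimators and the pipeline's wiring, not the
substantive theory; conversely `planted_loop_census()` gives every loop
analysis an exact expected answer, and the simulation tests confirm that
looped symptoms end up more frequent and that loop counts track burden.

## Numerical and scale choices

* Bootstrap and permutation routines take mandatory seeds and restore the
  global RNG state; identical inputs give byte-identical outputs.
* Percentile CIs use empirical quantiles (type 7); permutation percentiles
  likewise.
* Singular designs name their collinear columns instead of silently
  dropping them; constant predictors and moderators are rejected up front.
* Problem sizes in the test suite are chosen to keep the full suite around
  three minutes: oracle equivalences run on hundreds of random graphs of
  ≤ 6 nodes where exhaustive enumeration is exact; estimator recovery uses
  n = 2000--5000 with analytic SE bounds; interval coverage uses 200
  replicates of n = 500 with 1,000 resamples; the loop-coherence check uses
  20 seeded populations of n = 500.
* The pipeline (`run_pipeline()`) fans one global seed out as
  seed + 1 (simulation), + 2 (bootstrap models), + 3 (permutation/layout),
  so enabling or disabling stages never shifts another stage's stream.

## Limitations

PCR ratings are perceptions; nothing here estimates actual causal
structure, and the package deliberately contains no causal-discovery
machinery. Group mean networks average over heterogeneous individuals, and
edges with tiny support are only mitigated by `min_n`. The permutation
null tests weight arrangement, not sampling variability of the means; a
case-resampling bootstrap over participants would answer a different
question and is not implemented. Partial Spearman via ranked Pearson is an
approximation whose p-values lean on the t approximation under ties.
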