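# pcrnet

Analysis of **Perceived Causal Relations (PCR) scaling** data: how people
rate the causal connections among their own psychological symptoms, and
what the resulting directed symptom networks imply.

In a PCR survey each respondent rates the past-month frequency of 40
symptoms (ordinal 0–7) and then, for every ordered pair of endorsed
symptoms, answers "How much do you think your problems with X cause your
problems with Y?" on a 0–10 scale — both directions of every pair. The
design yields sparse directed rating matrices with two typed kinds of
missingness (never asked *by design* vs skipped *by intention*), and a
family of questions this package operationalizes for researchers in
psychopathology, comorbidity and symptom-network analysis:

* Is a symptom perceived more as a **cause** or as an **effect**? Per
  symptom, the mean causal association score C (average outgoing rating)
  is contrasted with the mean effect association score E (average
  incoming rating) by paired t test, with effect size
  `d = |t| / sqrt(df + 1)` and Holm–Bonferroni control across the 40
  comparisons.
* Do PCR scores **moderate** the association between symptom frequencies
  (y ~ x + w + x·w with simple slopes at ±1 SD), **increment** it
  (hierarchical ΔR² F test), or **mediate** it (indirect effect a·b with
  percentile-bootstrap CIs)? A moderated-mediation design combines both:
  conditional indirect effects (a1 + a3·w0)(b1 + b3·v0) over a moderator
  probe grid.
* What does the **group-level causal network** look like? Edges are mean
  PCR ratings over the participants who rated each pair; node centralities
  (weighted outdegree, indegree, and betweenness over inverse-weight path
  costs, Brandes/Dijkstra) are tested against permutation nulls built from
  1,000 weight-permuted networks.
* Do **causal feedback loops** matter? Per participant, the simple
  directed cycles of 2–4 symptoms among ratings above 4.5 are enumerated
  exactly (bounded-depth DFS, canonical rotation), and the per-participant
  loop count is related to the symptom frequency sum score by Spearman's
  rho, partialling out symptom and rating counts.

Because respondent-level PCR data sets are generally not public, the
package ships a seeded synthetic-population generator
(`simulate_population()`) with a known ground-truth causal weight matrix —
planted feedback loops included — so that every analysis stage has an
exact recovery test.

## Worked example

```r
library(pcrnet)

sim <- simulate_population(simulation_config(n_participants = 120, seed = 1))

# Is "anxious worrying" perceived more as a cause than an effect?
res <- cause_effect_comparison(sim$records, symptom = 2)
res[, c("n", "c_mean", "e_mean", "r_ec", "t", "df", "p", "d")]
#>    n c_mean e_mean  r_ec    t df       p    d
#> 1 80   1.32   1.16 0.141 3.31 79 0.00141 0.37

# Feedback loops above the 4.5 rating threshold, and symptom burden
census <- loop_census(sim$records, cutoff = 4.5, max_len = 4)
census$total_incidences; census$unique_loop_types
#> [1] 166
#> [1] 32
loop_burden_association(census, sim$records)
#>               analysis  rho       p  df defined
#> 1         unpartialled 0.61 1.4e-13 118    TRUE
#> 2     partial_symptoms 0.38 2.3e-05 117    TRUE
#> 3 partial_symptoms_pcr 0.37 4.6e-05 116    TRUE
```

Of the 120 simulated respondents, 80 rated worrying in both directions;
they attribute more causality to it than they ascribe to other symptoms
acting on it (C = 1.32 vs E = 1.16, t(79) = 3.31, d = 0.37) — worrying is
planted as a cause in the generator's ground truth. Loop counts correlate
strongly with total symptom frequency (rho = 0.61) and the association
survives partialling out the number of endorsed symptoms and of PCR
ratings (rho = 0.37), the signature of the planted feedback loops.

## Analysis workflow

The `analysis/` directory holds the end-to-end study pipeline as numbered
drivers over the package, each writing its tables under `results/`:

1. `01_simulate.R` — synthetic population of 288 respondents (CSV + ground
   truth JSON);
2. `02_descriptives.R` — the 40-row cause-vs-effect table with Holm
   control;
3. `03_models.R` — moderation, incremental, mediation and
   moderated-mediation models (10,000 bootstrap resamples, 98.33% CIs);
4. `04_network.R` — mean-PCR network, thresholds 3 / 4.5, centralities
   with 1,000-network permutation nulls, GraphML export and layout;
5. `05_loops.R` — per-participant loop census, symptom involvement,
   burden association, and recovery check against the planted loops.

`run_pipeline(pipeline_config(seed = ...))` runs the same stages
programmatically with one fanned-out seed.

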