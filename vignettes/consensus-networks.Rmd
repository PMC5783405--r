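---
title: "Consensus Bayesian networks for microbiome-survey studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus Bayesian networks for microbiome-survey studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnconsensus)
```

# The problem

Cross-sectional microbiome studies routinely collect three kinds of data on
the same subjects: taxon counts from 16S rRNA gene sequencing, extensive
categorical questionnaires (sexual, sanitary and birth-control habits,
health history), and clinical measurements (vaginal pH, the Nugent score —
a 0–10 microscopy score used as a bacterial-vaginosis diagnostic).
Ordination-based methods (NMDS/ANOSIM, PERMANOVA) compress the community to
a few axes and test metadata variables one at a time, so they cannot say
*which* taxon a habit is associated with, nor expose metadata–metadata or
taxon–taxon structure. A discrete Bayesian network over all variables at
once addresses exactly that: every variable is a node, and directed arcs
summarise the conditional-dependence structure the data support.

`bnconsensus` implements that analysis as a reusable, tested pipeline:

1. **data preparation** — depth filtering, screening-question exclusions,
   proportional normalization to the minimum depth, rare-taxon removal,
   presence/absence dichotomization, survey missingness/sparseness
   filters, and fixed discretization bins;
2. **structure learning** — BDeu-scored greedy hill climbing under
   root/leaf constraints, with the imaginary sample size estimated by
   alternating optimization;
3. **consensus** — a seeds-by-bootstraps ensemble of learned networks pooled
   into arc-support frequencies and thresholded into an averaged DAG;
4. **parameters and queries** — maximum-likelihood conditional probability
   tables and exact conditional queries by variable elimination;
5. **network analysis** — density, degree, normalized closeness and
   betweenness, Markov blankets, Louvain communities;
6. **companion analyses** — Hellinger transform, NMDS, ANOSIM and
   PERMANOVA with forward stepwise selection, for comparison with the
   ordination tradition;
7. **synthetic data** — a layered generator that emulates the statistical
   structure of such a study, so recovery can be quantified end to end.

# The model

## Scoring

For a discrete dataset with complete cases, the quality of a candidate DAG
$G$ is the log marginal likelihood of the data under Dirichlet parameter
priors (the BDe score). With the uniform BDeu prior, an imaginary sample
size $\alpha$ is split evenly over the cells of each node's
child-by-parent-configuration table: for node $i$ with $r_i$ levels and
$q_i$ parent configurations,

$$
\log P(D \mid G) \;=\; \sum_i \sum_{j=1}^{q_i}\!\left[
\log\frac{\Gamma(\alpha/q_i)}{\Gamma(\alpha/q_i + N_{ij})}
+ \sum_{k=1}^{r_i}
\log\frac{\Gamma(\alpha/(r_i q_i) + N_{ijk})}{\Gamma(\alpha/(r_i q_i))}
\right],
$$

where $N_{ijk}$ counts subjects with node $i$ at level $k$ and parents in
configuration $j$. This score is decomposable (a sum of per-node terms) and
likelihood-equivalent: Markov-equivalent DAGs score identically, which the
test suite checks explicitly on 2- and 3-node equivalence classes, and the
local terms are verified against an independent sequential
posterior-predictive oracle.

The imaginary sample size is not fixed a priori. `estimate_alpha_star()`
alternates between (a) learning a structure at the current $\alpha$ and (b)
maximizing the network score over $\alpha$ by one-dimensional search on a
log scale over $[10^{-2}, 10^2]$, stopping when $\alpha$ moves by less than
$10^{-3}$ or after 10 rounds. The interval, tolerance and a fixed-$\alpha$
override are exposed because the estimator is an internal design choice of
this package, not a canonical definition.

## Search

`hill_climb()` starts from the empty graph (plus any required arcs) and
greedily applies the single-arc addition, deletion or reversal with the
largest positive score gain, subject to acyclicity and the structural
constraints, until no move improves the score. Domain knowledge enters only
through roles: demographic roots (age, ethnicity) may have no incoming
arcs, and the diagnostic leaf (Nugent score) may have no outgoing arcs.
There is no tabu list, no parent-count cap and no random restart within a
run; restarts are the job of the ensemble. The seed controls tie-breaking
among exactly equal-gain moves (via a seed-derived priority matrix), so a
single run is deterministic and different seeds can walk different
plateaus. The accepted-move trace is attached to the result and the suite
asserts the score never decreases along it.

## Consensus

`bootstrap_ensemble()` learns one network per (search seed, bootstrap
resample) pair — the study-scale default is 1,000 seeds × 1,000 bootstraps;
tests and the acceptance script use scaled-down ensembles (tens by tens) —
and pools the ensemble into per-pair *support* (fraction of networks with
an edge between the pair in either direction) and per-direction frequency.
`averaged_network()` keeps pairs with support at or above the threshold
(0.30, and 0.50 as a majority rule) and orients each by majority direction.
Thresholding support rather than directed-arc frequency reflects the fact
that edge presence is far more stable under resampling than orientation;
the direction of a consensus arc should be read as the majority vote of the
ensemble, not as causal.

Thresholding independently per pair can, in principle, produce a directed
cycle. The repair rule is explicit: delete included arcs in ascending order
of `support x direction` until the graph is acyclic, and record every
deletion on the result. On randomized adversarial strength tables the suite
asserts the output is always a DAG.

Master-seed handling uses a counter scheme: the master seed derives one
sub-stream per search seed, which derives one resampling seed per
replicate. Results are therefore bit-for-bit reproducible and independent
of any parallel execution plan.

## Parameters and queries

`fit_mle()` estimates each conditional probability table as
$(N_{jk} + s)/(N_j + s\,r)$ with pseudo-count $s = 0$ by default (pure
maximum likelihood). With $s = 0$ a parent configuration that never occurs
in the data has no defined conditional distribution; the package maps it to
the uniform distribution, warns, and records the affected nodes — a
documented fallback, not a silent imputation. A CPT enumerates the full
parent-level product, so fitting refuses nodes whose parent-configuration
count exceeds $2^{20}$ with a clear error; in practice this only arises
when a low support threshold on a small, dense ensemble leaves a node with
very many parents, and the remedy is the sparser majority-rule (0.50)
consensus, which is also the natural choice for inference.

`query()` computes exact posteriors by variable elimination with a
min-degree elimination ordering. At this problem size (60 nodes, mostly
binary, small parent sets) exact inference is cheap and deterministic,
which we prefer over stochastic (logic-sampling) queries; a sampling mode
(`method = "sampling"`) is provided for cross-checking, and the suite
verifies exact inference against full joint enumeration on hundreds of
random networks to $10^{-10}$. `parent_sweep()` evaluates a node's
conditional probability over the full grid of its parents' states — the
computation behind "which parent-state combinations make a high Nugent
score certain" style summaries.

## Network analysis

Density uses the directed formula $|A| / (n(n-1))$. Degree, closeness,
betweenness and communities are computed on the undirected projection,
because consensus orientation is the least stable part of the estimate and
the visual-analytics convention for these summaries treats edges as
undirected. Closeness uses Freeman normalization with a reachable-fraction
correction, $(m/(n-1)) \cdot (m/\sum d)$ where $m$ counts reachable nodes —
necessary because a thresholded consensus can be disconnected (an isolated
node scores 0). Betweenness is normalized by $(n-1)(n-2)/2$ and checked
against a path-enumeration oracle. Communities come from Louvain modularity
optimization (resolution 1.0, unweighted), with labels canonicalized by
each community's smallest member so partitions are comparable across runs.

## Companion ordination statistics

The comparison analyses run on the filtered, normalized,
*non-dichotomized* counts: Hellinger transform (square root of relative
abundances), Euclidean distances (then equal to Hellinger distances), NMDS
in two dimensions with multiple random starts (Kruskal stress-1), ANOSIM
with free label permutation, and PERMANOVA expressed as redundancy analysis
on the transformed matrix — Euclidean-on-Hellinger makes the
distance-based and variance-partition formulations equivalent. These steps
are delegated to vegan (`decostand`, `metaMDS`, `anosim`, `rda` +
`anova.cca`), with the package's own wrappers fixing seeds and tidying
outputs, and the suite checking them against hand-computed rank and
sums-of-squares oracles.

Forward stepwise selection is hand-written because there is no canonical
AIC for multivariate RDA. The analog used is
$n \log(\mathrm{RSS}/n) + 2\,\mathrm{rank}$, with RSS the residual sum of
squares of the multivariate linear fit and rank the model-matrix rank;
selection adds the candidate that lowers this most and stops when nothing
does. "Forward" is a deliberate reading of the ambiguous phrase "forward
elimination": it matches the stepwise-selection idiom of adding terms from
the null model, and it is deterministic.

# The synthetic-data generator

`simulate_study()` emulates the statistical structure the pipeline assumes,
not any particular cohort:

* a **layered causal structure**: two demographic roots (age with 3 levels,
  ethnicity with 4), a layer of habit and taxon-presence nodes, a layer of
  symptom nodes plus binary vaginal pH, and the 3-level Nugent leaf; arcs
  only run forward across layers, with at most 3 parents per node so CPTs
  stay estimable at a few hundred subjects;
* **counts**: present taxa get negative-binomial reads with taxon-specific
  log-normal abundance weights, scaled to a per-sample depth drawn
  log-normally around a median of ~2,150 (matching the right-skewed,
  depth-variable character of 16S libraries); a handful of samples are
  forced below the 1,000-count depth filter, and 220 rare nuisance taxa are
  added with per-taxon grand totals guaranteed below the 0.1% rule;
* **survey**: the informative questions pass through as categoricals, four
  habit variables and age/Nugent are rendered as *numeric* values drawn
  within their true bin (so the fixed discretization recovers the level
  exactly, giving an exact end-to-end recovery invariant); screening
  questions (overall health, toxic shock) and filler questions destined for
  the missingness and sparseness filters are appended;
* **missingness**: MCAR cell masking at 0.5% — the rate implied by losing
  roughly a quarter of subjects to complete-case filtering over ~56
  retained questions — with designated high-missingness questions masked
  above the 5% threshold. MCAR suffices because the pipeline drops
  incomplete subjects, making the mechanism immaterial to correctness
  testing.

Effect strength is parameterized through the Dirichlet concentration of
CPT rows: concentration $(1 - e)/e + 0.02$, so $e \to 1$ gives
near-deterministic conditionals and $e \to 0$ near-independence. A
`level_floor` mixes rows with the uniform distribution, bounding every
level probability away from zero; the study emulation uses 0.2 (survey
answers are never deterministic in practice, and retained levels must
plausibly clear the 5% sparseness rule), while recovery experiments use
0.05 so that strong effects remain strong but no node degenerates to a
constant column.

What the generator does **not** emulate: real taxon co-abundance structure
beyond the sampled DAG, compositional coupling between taxa, non-random
missingness, or any specific cohort's marginal distributions. Passing the
recovery tests therefore demonstrates that the estimator recovers the kind
of structure it assumes, at realistic sizes — not that any particular
biological finding is correct.

# Numerical choices and degenerate inputs

* Normalization is deterministic proportional scaling, not rarefaction:
  it is reproducible and conserves within-sample proportions exactly.
  Presence is *any* positive (possibly fractional) normalized count.
* The rare-taxon rule is a grand-total share below 0.1% on the normalized
  table. An alternative reading — 0.1% of the pre-normalization median
  depth ("fewer than an average of 2 reads per sample") — can retain a
  different taxon set; the threshold is exposed as `frac` so either
  operationalization can be configured, and the grand-total-share reading
  is the default.
* Filter order is fixed: depth → subject exclusions → normalization →
  rare taxa → dichotomization → question missingness → complete case →
  level sparseness → discretization. Boundary conventions: a question with
  *exactly* 5% missing is kept; a level with exactly 5% of subjects is
  kept; a question with a single observed level is treated as maximally
  sparse and dropped.
* Score comparisons use a positive-gain tolerance of $10^{-8}$ so
  floating-point noise cannot drive endless plateau walks; exact ties are
  resolved by the seed's priority matrix.
* Zero-probability evidence in `query()` is an error, never a silent NaN;
  empty datasets score 0 under BDe (all Gamma terms cancel).
* In `averaged_network()`, an exact 0.5/0.5 direction tie orients towards
  the lexicographically smaller parent name — an arbitrary but stable
  convention.

# Problem sizes used in the tests and acceptance script

Checks run at sizes chosen to exercise the estimator honestly while
remaining desk-scale: property oracles at ≤3 variables × ≤8 rows and ≤20
total states; recovery at 15 nodes, n = 2000, 100-network ensembles;
parameter recovery at n = 10,000; calibration at 500 replicates × 199
permutations; the full study emulation at 394 subjects × 60 retained
variables with a 36-network consensus (at the estimated imaginary sample
size, bootstrap-resampled networks are dense and each search is costly, so
the emulation uses a smaller ensemble than the 15-node recovery runs). The study-scale ensemble (10^6
networks) is the documented default of `bootstrap_ensemble()` but is not
run in the tests.

# Known limitations

* Presence/absence dichotomization discards abundance information; the
  package deliberately mirrors that choice rather than extending it, since
  zero-inflated skewed counts fit neither the multinomial nor the Gaussian
  node models.
* Consensus arc directions are majority votes over a bootstrap ensemble
  and must not be read causally; reported associations are conditional
  dependencies.
* The alternating imaginary-sample-size estimator is a pragmatic
  implementation of an under-specified procedure; it is exposed with a
  fixed-$\alpha$ override precisely so sensitivity can be checked.
* With pure MLE parameters, conditional probabilities read off sparse
  parent configurations have large sampling error; the smoothing parameter
  `s` exists for that reason, and query results on configurations with few
  supporting subjects deserve scepticism.

# A minimal end-to-end run

```{r example, eval = FALSE}
library(bnconsensus)

sim <- simulate_study(sim_config(master_seed = 1))
prep <- prepare_data(
  sim$counts, sim$survey,
  exclusions = list(
    list(question = "good_health", disqualifying = "no"),
    list(question = "ever_tss", disqualifying = "yes")
  ),
  discretize = c(
    age = "age", nugent = "nugent", menarche_age = "menarche_age",
    partners_60d = "partners_60d", vaginal_births = "vaginal_births",
    period_length = "period_length"
  ),
  categories = sim$categories
)

alpha <- estimate_alpha_star(prep$dataset, seed = 2)$alpha
strengths <- bootstrap_ensemble(prep$dataset, alpha = alpha,
                                n_seeds = 10, n_boot = 10, master_seed = 3)
consensus <- averaged_network(strengths, threshold = 0.30)

fit <- fit_mle(consensus, prep$dataset)
query(fit, "nugent", list(ph = ">4.5"))
metrics_report(consensus, variable_categories(prep$dataset))
```
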