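---
title: "Models and methods behind mllscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mllscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mllscape)
```

mllscape implements the computational core of a proteomic and functional-genomic
survey of MLL-fusion proteins: scoring bait-specific interactions from
multi-channel AP-MS evidence, assembling and partitioning the conserved
interactome, scoring competitive-proliferation shRNA screens, and classifying
genes by a dual histone-mark signature from spike-in normalized ChIP counts.
This vignette explains the models, the tunable parameters and their defaults,
the design decisions taken where the design was genuinely open, and what the
synthetic-data generators do and do not emulate.

## The enrichment model for AP-MS evidence

Each AP-MS run measures, per prey protein $j$, a spectral count and two
search-engine peptide-score sums. All three evidence channels are modelled on
the log scale with the same linear predictor

$$\log \mathbb{E}[y_{i,k,j}] = A_{0,j} + A_{i,j} + \alpha_i + \beta_{i,k},$$

where $A_{0,j}$ is the log baseline abundance of prey $j$, $A_{i,j}$ its
specific enrichment in pulldowns of bait $i$, and $\alpha_i$, $\beta_{i,k}$
bait- and replicate-level terms absorbing the nonspecific background
proteome. Spectral counts are Poisson; the two score channels are log-normal
with a channel-specific residual sd. Each channel is fitted independently,
so constant channel offsets are absorbed into that channel's baselines.

Two anchors make the model identifiable:

* **Control runs** carry neither enrichment nor background terms
  ($A_{i,j} = 0$, $\alpha = \beta = 0$), so control data pin the baselines
  $A_{0,j}$.
* **Background preys** (DDX5/DDX17 analogues, ubiquitous in every run) are
  constrained to $A_{i,j} = 0$ in every bait, so their abundance in bait runs
  identifies $\alpha_i + \beta_{i,k}$. The split between $\alpha_i$ and
  $\beta_{i,k}$ is resolved by the hierarchical prior on $\beta$.

Priors are weakly informative on the log scale and overridable through
`inference_config()`: $A_{0,j} \sim N(0, 10^2)$, $A_{i,j} \sim N(0, 5^2)$,
$\alpha_i \sim N(0, 5^2)$, $\beta_{i,k} \sim N(0, \sigma_\beta^2)$ with
$\sigma_\beta \sim$ Half-Normal(1), and a Half-Normal(1) prior on the
log-normal residual sd.

### Inference

Sampling uses an owned, fully vectorized random-walk Metropolis-within-Gibbs
scheme. Besides per-parameter updates, two joint "ridge" moves are essential
for mixing: $\alpha_i \to \alpha_i + \epsilon$ with $A_{i,j} \to A_{i,j} -
\epsilon$ (whose acceptance is driven only by the background-prey cells), and
the analogous move between $A_{0,j}$ and the $A_{\cdot,j}$ column (driven by
control runs). The exact decomposition of $\alpha_i + \beta_{i,k}$, along
which the likelihood is flat, is redrawn by a conjugate Gibbs step each
sweep. Step sizes adapt toward a 44% acceptance rate during burn-in only.
Convergence is monitored by split-$\hat R$ over chains; a maximum above the
threshold (default 1.05) triggers a warning and is recorded in the fit
metadata, never silently ignored. Defaults are 4 chains of 5,000 kept draws
after 2,000 burn-in iterations; the simulation studies below use 2 chains of
1,200 kept draws after 600, which already yield split-$\hat R$ < 1.05 on
those problems. On a tiny fixture the test suite cross-checks the posterior
against an independent general-purpose MCMC engine (JAGS) running the same
model.

### From posteriors to the interaction list

The evidence that prey $j$ binds bait $i$ is summarised as the posterior
tail probability $P(A_{i,j} \le 0)$, estimated from $n$ draws with the
add-one correction $(1 + \#\{A \le 0\})/(1 + n)$ so it always lies in
$(0, 1]$. The three channel p-values are combined by Fisher's method
($-2\sum\log p \sim \chi^2_{2k}$); a pair contributes only its observed
channels, so the degrees of freedom adjust instead of imputing missing
scores. Within each bait, pairs are ranked by combined p-value with ties
broken lexicographically by prey identifier — determinism over elegance.
The published cascade then keeps the top 300 interactions per bait
(`select_top_interactions()`), retains preys shared by at least five baits
(`conserved_interactors()`), and removes a user-supplied manual exclusion
list; the identities of the seven manually removed proteins are not public,
so the exclusion list is an input.

## Network, communities, enrichment

Known protein-protein interactions are expanded from complex databases with
the matrix model (`complexes_to_pairs()`: all unordered member pairs).
Because curated complex collections are redundant, complexes sharing
strictly more than 70% of their proteins are iteratively merged first. The
overlap denominator is the smaller complex (overlap coefficient): a complex
nested inside a larger one is redundant, which matches the intent of the
rule. Pairwise merging is order-dependent, so the order is fixed — largest
complex first, ties by name — and the union takes a concatenated name;
merging is idempotent.

`assemble_network()` joins bait-prey edges with known edges restricted to
the conserved set, removes self-interactions, and splits non-bait nodes
into a connected core (with at least one known edge) and bait-only nodes.
Communities are found on the known-edge subgraph only: bait hubs touch
every node and would dominate the degree-preserving null of the modularity
score $Q = \sum_c \left(e_c/m - (d_c/2m)^2\right)$. Up to `exact_limit`
(default 10) nodes the partition search is exhaustive over all set
partitions (Bell(10) = 115,975), enumerated as restricted-growth strings;
ties keep the lexicographically smallest canonical labelling. Larger graphs
use the deterministic greedy agglomerative heuristic. True optimal
modularity at the scale of a ~130-node network requires integer
programming; the exact-versus-greedy split here is a stated approximation.
Nodes without known edges cannot be placed by modularity;
`assign_unconnected()` implements a labelled heuristic — a node joins the
community whose top enriched term annotates it, ambiguity leaves it
unassigned.

Annotation and complex enrichment is a one-sided Fisher exact test
(hypergeometric upper tail) over a generic term-to-protein map against an
explicit background population, with Benjamini-Hochberg adjustment across
tested terms. Topology-weighted GO algorithms are out of scope; flat Fisher
is the implemented contract.

## Screen scoring

Competitive-proliferation trajectories (GFP% over time) are normalized to
the measurement after two days of induction, summarised at the final common
day (day 14 in the default design), and linearly rescaled between the
negative control (flat, score 0) and the strongly depleting positive
control (score 1). Stronger depletion therefore maps to larger scores, and
z-scores over screened genes (population sd, controls excluded) are
positive for stronger depletion. The z-score formula is not printed in the
source study; standard standardization with that sign convention is the
implemented contract. Fusion-context selectivity is a difference of
context means — not a ratio, because wild-type depletion of neutral genes
is near zero. Essentiality aggregation sums binary calls across 18
published screens and flags genes scoring in at least 10. The comet-assay
tail moment (mean migration distance times tail-DNA fraction) is included
as the damage metric used alongside the screens.

## ChIP signature

Spike-in factors divide the smallest exogenous-read total by each
library's total, so every factor is at most one (downscaling only; the
reference constant is a documented choice, as only the tool — not the
constant — is public). The high/low call per gene and mark compares
spike-in-scaled IP counts against scaled input strictly: equality does not
exceed the input and is low. Whether the published analysis applied the
rule before or after TMM is not stated; this package applies it to
spike-in-scaled, input-compared counts and exposes TMM as an optional
extra step. `tmm_factors()` uses the canonical trim fractions (30% on
M-values, 5% on A-values) with precision weights; unlike library-size
relative implementations, its factor folds the depth difference in
(doubling a column halves its factor), and factors multiply to one. The
dual signature flags genes high for both H3K36me3 and H3K79me2;
`dual_signature_fraction()` reports the fraction per labelled gene set,
and `mark_correlation()` is plain Pearson.

## What the generators emulate — and what they do not

Every module ships a ground-truthed generator so the pipeline is testable
without downloads; all generators are pure functions of their configuration
and an explicit seed (no global random state).

* `simulate_apms_dataset()` is the enrichment model read forward, with
  sparse positive effects, bait/replicate background terms, and elevated
  baselines for the designated background preys. Score channels are drawn
  log-normal around the same linear predictor plus a channel offset — the
  score-generating process of real search engines is not public, only the
  modelling assumption. When a spectral count is zero both score values
  are emitted missing, mirroring an undefined peptide-score sum. Defaults
  (7 baits, 200 preys, 3 replicates per bait, 3 control runs, 25 true
  interactors per bait with 40% drawn from a conserved pool, log baseline
  1.5 ± 1, log effect 2.5 ± 0.5) were chosen once as a desk-scale analogue
  of a seven-bait nuclear interactome survey with spectral counts mostly
  in single digits to tens. Replicate and control-run counts are not
  published; they are configuration.
* `simulate_complex_db()` plants recorded near-duplicate complexes (>70%
  overlap) for the merging tests; `simulate_screen()` uses multiplicative
  per-interval depletion truncated to [0, 100], with the positive control
  depleting at the same per-interval rate as essential genes (it is itself
  an essential-gene control), which makes zero-noise essential genes score
  exactly 1; `simulate_chip_counts()` assigns dual-high status with the
  emulated probabilities (0.76 for MLL-target genes, 0.42 otherwise) and
  draws IP counts at a two-fold enrichment over input for high genes and
  half input for low genes, through the spike-in depth of each library.
* What they do **not** emulate: peptide-to-protein inference, search-engine
  score distributions, contaminant spectra, batch effects, cell-line
  heterogeneity, read-level ChIP noise or fragment-length effects. Passing
  recovery tests therefore demonstrates correctness of the statistical
  machinery under its own assumptions, not robustness to every artefact of
  real data.

## Numerical choices and problem sizes

Simulation studies are sized for a desk machine: the null-calibration run
(7 baits x 200 preys x 3 replicates, all three channels) and the recovery
run (defaults plus planted effects) each take on the order of ten seconds
with 2 chains x 1,200 kept draws. In the scaled-down recovery analysis the
top-k cut uses k = 28 per bait, preserving the published selection
fraction (300 of roughly 2,150 candidate interactions per bait) at 200
preys. Percentages that mirror printed cascade numbers round half away
from zero to one decimal. Exhaustive partition search is capped at 10
nodes; the two-triangle reference graph has a known optimum of Q = 0.5.
Posterior tail p-values use the add-one correction; Fisher combination
requires p-values strictly in (0, 1], which that correction guarantees.

## Known limitations

Single-dataset null calibration of the combined p-value is slightly
overdispersed relative to a binomial reference because baseline and
background estimation errors are shared across the pairs of a prey or a
bait; calibration holds in expectation across datasets. The greedy
community heuristic can miss the global modularity optimum on graphs just
above the exact limit. The enrichment model assumes independent channels
given the linear predictor; correlated search-engine scores would make
Fisher's combination optimistic. None of these affect the deterministic
operations (filtering, merging, scaling, classification), which are exact.
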