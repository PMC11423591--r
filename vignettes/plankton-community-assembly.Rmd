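---
title: "Assembly processes, niche breadth and network stability of plankton microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly processes, niche breadth and network stability of plankton microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

planktonet asks how plankton communities are put together along coastal
environmental gradients: how much of the observed taxonomic and
phylogenetic turnover between stations is driven by deterministic
environmental selection, how much by dispersal and drift, and what that
implies for the complexity and stability of the co-occurrence networks the
taxa form. The package covers the full chain from a count table, a rooted
phylogeny and station metadata to process fractions, network topology and
removal-based stability, and ships a synthetic-data generator with known
ground truth so that every stage can be validated end to end.

This vignette documents the models, the tunable parameters, and the design
choices made where the methodology left genuine freedom.

## Sub-community partitioning

Features are first screened with the standard prevalence/count filter
(present in at least 2 samples and at least 5 reads in total), optionally
rarefied to a common depth, and classified as **abundant** (per-sample
relative abundance above 1% in at least 10% of samples, or summed relative
abundance above 20%), **rare** (summed relative abundance below 0.5%), or
**moderate** (the remainder).

"Summed relative abundance" is ambiguous in the rare-biosphere literature:
some authors sum the per-sample proportions across samples, others use the
mean. `classify_abundance_groups()` defaults to the literal sum
(`sum_convention = "total"`), under which the abundant and rare rules are
provably disjoint whenever there are at least five samples (the occurrence
route to "abundant" forces a summed abundance of at least 0.1 x n samples
percent). The mean convention is available as an option; because the two
rules can then overlap, a feature satisfying both raises an error rather
than being silently assigned.

## Alpha diversity, Mantel tests and niche breadth

Shannon diversity is reported in natural logarithms, with Pielou evenness
J = H / ln S (undefined, and flagged `NA`, for single-taxon samples).
Faith's phylogenetic diversity includes the path to the root, the most
common convention. Bray-Curtis dissimilarities are computed on counts by
default (identical to proportions for rarefied tables).

`mantel_test()` correlates lower triangles of two distance matrices with
permutation p-values, `p = (1 + #[r_perm >= r_obs]) / (1 + n_perm)`. It
defaults to Spearman correlation, the rank-robust choice; Pearson is
available. For station-by-station environmental comparisons the pipeline
builds single-variable Euclidean distances on z-score-standardised
variables, so that each variable's Mantel r is scale-free; geographic
distance is Euclidean on (longitude, latitude) in degrees by default, with
great-circle kilometres as an option. Samples with missing values in a
variable are dropped pairwise and the count is logged.

Levins niche breadth for feature j uses abundance-based usage proportions
across samples, `B_j = 1 / sum_i P_ij^2`, ranging from 1 (one station;
specialist) to the number of stations (even spread; generalist). Group
summaries aggregate B by abundance class.

## The Sloan neutral community model

Under neutral assembly, the relative abundance of a taxon with
metacommunity mean p follows `Beta(N m p, N m (1 - p))` in a local
community of N individuals with immigration probability m. Its expected
occurrence frequency across samples is the probability of detecting it.
`fit_ncm()` fits the single parameter m by bounded nonlinear least squares
(`minpack.lm::nlsLM`, with an `optimize()` fallback) and reports m,
Nm, and `R^2 = 1 - SSE/SST`, plus Wilson 95% bounds around the predicted
frequencies.

The detection model deserves care. The classic implementation predicts
detection as the Beta tail above a sharp limit d = 1/N. For communities
observed by sequencing N reads, however, detection is a sampling event with
probability `1 - (1 - x)^N` given true relative abundance x, which smooths
the transition around 1/N. In simulate-and-recover experiments against the
package's own sampling-based generator the sharp-threshold fit
overestimates Nm by roughly 30%, while the exact beta-binomial prediction

$$\hat f(p) = 1 - \frac{B(a,\, b + N)}{B(a,\, b)}, \qquad a = Nmp,\; b = Nm(1-p)$$

(the probability of at least one read, in closed form, with no additional
parameters) recovers Nm to within a few percent. `fit_ncm()` therefore
defaults to `detection = "binomial"` and retains
`detection = "threshold"` for comparability with the classic variant. N
defaults to the mean sample total, which equals the rarefaction depth on
rarefied tables.

## Phylogenetic null models and process classification

SES MNTD, beta-MNTD and beta-NTI quantify within- and between-community
phylogenetic structure. Beta-MNTD is abundance-weighted by default, the
convention under which the +/-2 thresholds of the beta-NTI framework were
calibrated; the unweighted variant is available. The null model shuffles
taxon labels on the cophenetic distance matrix ("taxa.labels"); in
`beta_nti()` one permutation per replicate is applied to the whole matrix
and every sample pair is re-evaluated under it, which makes 199-999
replicates tractable at two thousand taxa (the inner loops are implemented
in C++; the implementation is tested for exact agreement against an
independent brute-force double loop and against `picante::comdistnt`).
A null standard deviation below 1e-12 marks a degenerate pair (for
example, a sample containing every tip); such pairs are flagged `NA` and
excluded from process fractions with a logged count.

Raup-Crick on Bray-Curtis reassembles each community at fixed richness and
fixed total abundance: taxa colonise with probability proportional to
their occupancy across the table, receive one individual each, and the
remainder is filled multinomially in proportion to pool abundances. The
score is rescaled to [-1, 1] with ties counted half. The regional pool
(occupancy and pool abundance) is estimated from the table by default but
can be supplied explicitly — reassembling a table from the null model
flattens its occupancy distribution, so a self-calibration of the score is
only exact when the generating pool is held fixed.

Pairs are classified with the standard two-stage rule: beta-NTI below -2,
homogeneous selection; above +2, variable selection; otherwise Raup-Crick
above +0.95, dispersal limitation; below -0.95, homogenising dispersal;
else undominated drift. All four thresholds are arguments.

## Co-occurrence networks

`build_network()` computes pairwise correlations (Spearman by default) on
log10-transformed relative abundances on the percent scale, replacing
zeros with a pseudo-abundance of 0.01 before the log — the convention of
the molecular ecological network pipelines. Features must pass an
occupancy filter (at least half the samples by default). An edge requires
both `|r| >= r_min` (default 0.6) and a Benjamini-Hochberg adjusted
p-value at most `q_max` (default 0.05), computed from the t approximation;
the sign is retained as an attribute. The random-matrix-theory threshold
scan of those pipelines is deliberately not re-implemented: an explicit,
configurable threshold contract is transparent at 38-station scale, and
the construction parameters are recorded in the graph attributes.

Modules come from deterministic fast-greedy modularity optimisation on the
unweighted topology; because greedy agglomeration can terminate above the
trivial optimum on very dense graphs, the connected-component partition is
also evaluated and the better of the two is returned. Node roles use the
within-module degree z-score Zi and participation coefficient Pi with the
Guimera-Amaral cutoffs (module hub Zi >= 2.5, connector Pi >= 0.62,
network hub both). Betweenness is normalised by (n-1)(n-2)/2. Degree
distributions are checked against a power law by least squares on log
frequency versus log degree; fewer than five distinct degrees is flagged
not assessable.

## Stability

Robustness is the proportion of taxa remaining after node removal plus
secondary extinction: after removing a random fraction (or half of the
module hubs), any survivor left without a single edge is counted extinct.
The cascade needs only one pass, since removing an isolated node cannot
isolate another; a no-cascade variant is available. Vulnerability of node
i is the relative drop in global efficiency (mean inverse shortest path
over ordered pairs, unreachable pairs contributing zero) when i is
removed; network vulnerability is the maximum over nodes, and peripheral
nodes can legitimately score negative. The fragmentation series removes,
at each step, the current highest-betweenness node — recomputed after
every removal, with ties broken by higher degree and then lexicographic
id for reproducibility — and records both the component-pair
disconnection probability `F = 1 - sum_k s_k (s_k - 1) / (N_r (N_r - 1))`
and the largest-component share, since the literature uses both and the
choice is not standardised.

## The synthetic-data generator

The generator is the package's ground truth and defines the conditions
under which the methods are validated:

* **Source pool.** Proportions are normalised Gamma(shape) draws — a
  symmetric Dirichlet, the exchangeable form of the log-series family.
  The default shape 0.1 reproduces the skew of coastal amplicon surveys:
  at survey scale roughly three quarters of the pool sits below the rare
  cutoff and a few tens of taxa are abundant.
* **Neutral sampling.** Each sample draws per-taxon latent relative
  abundances from the Sloan Beta marginal and one multinomial of size N.
  This is a sampling-based route, independent of the CDF-based fitter, so
  generator and fitter cross-validate one another.
* **Selection.** Each taxon has a Gaussian niche on the standardised
  latitude gradient. Optima evolve by Brownian motion on the tree and are
  rank-mapped uniformly onto the gradient, so clades share niches
  (the condition for beta-NTI to respond) while the landscape always
  covers the gradient. `phylo_signal = FALSE` shuffles optima across
  taxa: selection still structures co-occurrence but phylogenetic
  turnover stays at its null expectation. `selection_strength = 0`
  reproduces the neutral generator bit for bit at equal seeds.
* **Guild dynamics and drift.** Optima can snap to a few discrete guilds
  (`n_guilds`) whose member taxa share synchronous lognormal fluctuations
  (`guild_noise`, bloom dynamics) — the mechanism that yields sparse,
  modular co-occurrence networks. Independent per-taxon lognormal noise
  (`drift_noise`) models ecological drift and unmeasured
  micro-environment.
* **Mixed mode.** Per-sample weights in [0, 1] interpolate between
  neutral and selective sampling and are recorded in the truth block.

`simulate_cross_kingdom_fixture()` emulates a 38-station two-kingdom
survey at 12,000 reads per sample: a mostly-neutral, eukaryote-like table
(weak selection, phylogenetically random optima, 14 guilds) and a
selection-driven, prokaryote-like table (phylogenetically conserved
selection, 8 guilds), sharing one metadata table. After dropping taxa
never observed, the tables hold roughly 2,000 and 1,800 features with
non-empty abundant classes and rare majorities. Pool sizes, read depth,
selection strengths and noise levels were calibrated once against that
target structure and are not meant as tuning knobs.

What the generator does **not** emulate: PCR/primer and copy-number
biases, chimeras or sequencing error (taxa are sampled, not sequenced),
temporal dynamics, direct species interactions (co-occurrence arises only
from shared responses and shared fluctuations), and spatially explicit
dispersal. Passing tests therefore demonstrate that the statistical
machinery recovers known structure from idealised surveys, not that any
particular biological conclusion transfers to real data.

## Numerical choices and problem sizes

All stochastic stages take explicit seeds and restore the caller's RNG
state; identical seeds give bit-identical outputs, and the pipeline
records seeds in its provenance block. Null replicate counts default to
999 with a `ci` profile at 199; degenerate nulls are detected at sd <
1e-12; the NCM migration estimate is constrained to [1e-6, 1] and flagged
when it hits a bound. The validation suite runs the simulate-and-recover
experiment at 50 samples x 200 taxa x N = 1000 over 20 seeds, the null
calibrations at 200 replicates with 199 shuffles each, the Mantel
type-I-error simulation at 500 independent 15-station matrix pairs with
999 permutations, and the cross-kingdom contrast at full fixture scale
over 20 paired seeds with the pairwise nulls evaluated on
gradient-extreme station pairs; the acceptance script evaluates the
complete assembly classification on a 16-station gradient-stratified
subsample of the fixture. These sizes were chosen to give stable
statistics while keeping a full run in the minutes range on a single
core.

## Known limitations

* The Spearman edge p-values use the t approximation, adequate at n >= 20
  but approximate in the presence of many ties.
* Raup-Crick nulls are re-drawn per pair rather than shared, so its cost
  grows with the number of pairs; for large surveys restrict `pairs` or
  subsample stations.
* The abundant/rare cutoffs are the survey conventions of the coastal
  literature; they are configurable but no attempt is made to infer them
  from the data.
* Process fractions inherit the thresholds' discreteness: near-threshold
  pairs flip classes under resampling, which is why the package reports
  fractions over many pairs rather than per-pair labels as conclusions.
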