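---
title: "Attacking symptom networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attacking symptom networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netattack)
```

## The question the package addresses

In the network view of psychopathology, a mental disorder is a weighted
graph: nodes are symptoms, edges are estimated pairwise interactions
(partial correlations for continuous measures, logistic couplings for
binary ones). If the disorder is sustained by the connectivity of this
graph, then treatments that deactivate well-chosen symptoms should
dismantle it faster than treatments that deactivate arbitrary ones.
`netattack` turns that hypothesis into a simulation: symptoms are removed
from the network one at a time — in descending order of a centrality
measure (degree, strength), a bridge measure (modular bridgeness, modular
overlap), or uniformly at random — and the damage done to the network is
tracked after every removal.

Three state metrics are recorded along each removal trajectory:

* **connectivity** — the number of interactions present (optionally the
  summed absolute edge weight);
* **components** — the number of disconnected pieces, isolated symptoms
  included;
* **average path length** — the mean shortest-path distance over
  connected ordered pairs, undefined once no edges remain.

Each trajectory is reduced to five outcomes: the *impact magnitude*
(peak minus initial value) for components and path length, the *attack
extent* (proportion of symptoms removed to first reach the peak) for the
same two metrics, and the extent to a 50% connectivity drop. Attack
conditions are then compared across networks with robust dependent-samples
tests.

## Ranking measures

Degree counts a symptom's nonzero connections; strength sums their
absolute weights. The two bridge measures come from an overlapping module
assignment. For a node $i$ with membership row $q_i$ over modules and
connection profile $\hat c_i$ (the distribution of its absolute edge
weight over the modules of its neighbors), both measures are the inverse
participation ratio ("effective number") $1/\sum_m p_m^2$ of the relevant
row: *modular overlap* is the effective number of modules the node belongs
to (trans-modular role), *modular bridgeness* the effective number of
modules it connects to (inter-modular role). A symptom shared between two
disorders scores high on overlap; a symptom of one disorder wired into
another scores high on bridgeness.

### The module backend

Published work in this area has used the ModuLand framework (a Cytoscape
plugin) to obtain fuzzy module assignments. Its internal landscape
algorithm is not part of what this package reproduces; we only need its
two outputs — fuzzy membership and a module connection profile — with
deterministic, testable behavior. The backend here is deliberately
simple:

1. **base partition** by greedy modularity maximization on absolute
   weights (`igraph::cluster_fast_greedy`);
2. **membership smoothing** by a damped random walk,
   $q^{(t+1)}_i = (1-\alpha)\,\mathrm{onehot}(\mathrm{base}(i)) +
   \alpha \sum_j P_{ij} q^{(t)}_j$, where $P$ is the $|w|$ row-normalized
   transition matrix, iterated to a fixed point (defaults $\alpha = 0.5$,
   at most 50 iterations, tolerance $10^{-6}$);
3. **connection profile** $\hat c_i \propto \sum_j |w_{ij}|\, q_j$,
   row-normalized.

No claim of numerical equivalence with ModuLand is made — the claim the
tests back is *ordinal*: on planted fixtures, the node shared between two
cliques attains the maximum modular overlap, and a clique-to-clique
bridge-edge endpoint attains the maximum modular bridgeness. One
consequence of anchoring the walk at a hard base partition is worth
knowing: a perfectly symmetric shared node does not converge to the
symmetric membership $(0.5, 0.5)$ but to roughly $(0.75, 0.25)$ at
$\alpha = 0.5$, because the anchor pins it to the module the base
partition chose. Its overlap (about 1.5) still dominates every
single-module node (about 1.1), which is the property the attack
orderings rely on. Negative weights enter all module computations through
their absolute values, consistent with strength.

## Attack protocol

The default (`initial`) protocol ranks symptoms once, on the intact
network, and removes them in that fixed order — the protocol used when
central and bridge symptoms are nominated as treatment targets from a
single network estimate. Ties are broken by ascending label so runs are
deterministic; seeded uniform tie-breaking is available. The
`recalculated` (cascading) mode re-ranks the surviving subnetwork before
every removal; it is provided as a first-class option because fixed
orderings are known to waste removals once the top-ranked symptoms'
connections are gone.

Removal continues until a single node remains (the stopping point is a
design choice; peak searches use the full recorded trajectory, so
stopping earlier could only truncate peaks). The random condition draws
uniformly random orders — 2,000 replicates by default — and each
replicate's five outcomes are averaged; averaging the state trajectories
first and reducing once is available as `method = "mean_trajectory"` for
sensitivity analysis. Replicate $r$ uses seed $\mathrm{base} + r$, so
enlarging the replicate set never reorders earlier replicates.

Connectivity defaults to the unweighted edge count — the literal reading
of "number of interactions" — with the summed-|w| variant exposed as
`weighted = TRUE`. Path length defaults to hop counting with disconnected
pairs excluded; `inverse_weight` treats strong edges as short.

## Estimating networks from raw data

When raw data rather than adjacency matrices are available, networks are
re-estimated the way current psychometric practice does:

* **continuous data** — graphical lasso over a log-spaced penalty grid
  (100 points, smallest penalty 0.01 of the one that empties the graph),
  model selection by EBIC
  $-2\ell + k\ln n + 2\gamma k \ln p$ with $\gamma = 0.5$; edge weights
  are the selected model's partial correlations
  $\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$. Only
  off-diagonal precision entries are penalized, the convention of
  EBIC-glasso estimation in this field. One deliberate choice: the EBIC
  is evaluated on the support-constrained *unpenalized* maximum
  likelihood refit of each candidate support, not on the penalized
  estimate itself. With the penalized likelihood, shrinkage bias makes
  the EBIC keep improving as the penalty shrinks and near-saturated
  models get selected; the refit (equally deterministic) restores the
  U-shaped criterion and accurate support recovery.
* **binary data** — the Ising model by nodewise L1-penalized logistic
  regressions (via `glmnet`), per-node penalty chosen by EBIC with
  $\gamma = 0.25$, edges reconciled with the AND rule (both directed
  coefficients nonzero; weight is their arithmetic mean), OR available.

Both $\gamma$ defaults follow the conventions of the standard tools for
these models; which settings any given published network used is
generally unreported, so both are configurable.

## Robust comparison of attack conditions

Outcome distributions across networks are skewed with extreme values, so
conditions are compared with 20%-trimmed means. The omnibus statistic is
the dependent-groups trimmed-means ANOVA $F_t$: the between-condition sum
of squares of trimmed means (scaled by $h = n - 2g$, $g = \lfloor 0.2
n\rfloor$) over the condition-by-network interaction sum of squares of
the Winsorized scores. Its critical value is the 95th percentile of the
same statistic over 2,000 bootstrap resamples of complete rows of the
column-centered data (each column minus its trimmed mean), preserving
the dependence among conditions; the test is significant when $F_t$
exceeds it. Post hoc tests report, for each pair of conditions, the
trimmed-mean difference (psihat, negative when the first condition's
trimmed mean is lower), a studentized statistic with
$SE^2 = (w_{jj} + w_{kk} - 2w_{jk})(n-1)/(h(h-1))$ from the Winsorized
covariance $w$, and one familywise critical value shared by all pairs —
the 95th percentile of the bootstrap distribution of the maximum $|T|$
over pairs — with confidence intervals $\hat\psi \pm c \cdot SE$.
Marginal (not difference-score) trimmed means are used, matching the
psihat definition. Rows with any missing condition are dropped listwise
with a logged count (path-length outcomes are undefined for networks
with no initial edges). The five outcome families are tested separately
with no cross-family multiplicity correction.

## What the synthetic generators emulate

The ensemble generator reproduces the descriptive profile of published
cross-sectional symptom networks: node counts from a log-normal
distribution matched to mean ≈ 23 and SD ≈ 21 and truncated to 5–120
(the published corpus reports only descriptives, not a distribution);
densities uniform on 0.067–0.861; signed weights with Beta(2, 5)
magnitudes and 90% positive edges, typical of partial-correlation
networks; connectedness not forced. Ground-truth generators provide
sparse positive-definite precision models (support uniform at a target
density, positive definiteness by a deterministic diagonal-loading
ladder to condition number at most $10^4$), Ising models with negative
thresholds offset against each node's positive coupling mass so marginal
activations stay non-degenerate, and planted clique fixtures with known
shared and bridging nodes.

What they do *not* emulate: the module structure, weight distributions,
or degree sequences of any specific disorder network; measurement error
and sampling variability of the original studies; ordinal item scales.
Passing tests therefore demonstrate that the machinery measures what it
claims on networks with known ground truth — not that any substantive
conclusion transfers to a particular clinical corpus.

## Numerical choices and degenerate inputs

* Peak ties resolve to the first attainment; extents divide by the
  *initial* node count.
* Steps whose surviving graph has no edges contribute an undefined
  sentinel (`NA`) to the path length and are skipped by peak searches.
* An edgeless network cannot be module-partitioned; `detect_modules`
  errors and the study loop skips such networks with a logged reason
  (the study aborts only if fewer than 5 networks survive).
* Winsorized pooled variances in bootstrap resamples can hit exact zero
  for degenerate columns; the corresponding bootstrap statistic is
  treated as 0 rather than NaN.
* Asymmetric adjacency input is symmetrized by averaging, with a
  warning.
* All generators and resampling loops take explicit integer seeds and
  restore the caller's RNG state.

## Problem sizes

The package's own test battery runs the full pipeline on a 51-network
synthetic ensemble with 2,000 random replicates per network and 2,000
bootstrap samples per comparison; on one CPU this completes in a few
minutes, dominated by the largest, densest networks (the per-step metric
kernel is compiled, with the surviving subgraph kept in a compacted
adjacency structure). Exhaustive enumeration oracles are used up to 7
nodes (5,040 orders).

## Known limitations

* The module backend is a specified stand-in chosen for determinism and
  testability; fuzzy memberships are anchored to a hard base partition,
  so overlap values are compressed toward 1 relative to a fully
  symmetric assignment (ordinal comparisons are unaffected on the
  fixtures tested).
* Edge-removal (interaction-inhibition) attacks are out of scope; only
  node deactivation is simulated.
* Betweenness and closeness orderings are deliberately not offered —
  they are unstable on networks of this size and were excluded from the
  study design this package implements.
* The Ising fit requires at least 3 symptoms (nodewise regressions need
  two or more predictors).
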