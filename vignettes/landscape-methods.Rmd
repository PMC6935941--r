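---
title: "Methods: trajectory backbones, landscape potentials, cell-type dynamics, and bursting kinetics"
author: "scLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory backbones, landscape potentials, cell-type dynamics, and bursting kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLandscape)
```

# Scope and data model

scLandscape analyzes a nonnegative cells × genes expression matrix
(`CellStateSet`) as a point cloud in cell state space. It infers, in
order:

1. a tree-shaped **backbone** of cell-state transition trajectories,
   by searching for pseudo-potential wells on super-rings (annuli);
2. a per-cell **pseudotime** in [0, 1], by projection onto that tree;
3. a quantitative **developmental landscape**: every cell gets a
   potential from the stationary distribution of a pseudotime-biased
   random walk;
4. **cell-type dynamics**: transition, exit, and fate probabilities
   over branch-level types and well-level subtypes;
5. pseudotime-windowed **marker-gene networks** and correlation-degree
   indices;
6. **transcriptional bursting kinetics**: per-gene Gamma maximum
   likelihood fits (mean burst frequency and size) along pseudotime.

All stages after the backbone consume only the pseudotime (and branch
labels), so orderings from other tools can be substituted via
`manualOrdering()`.

# The pseudo-potential and the super-ring search

The local density of a cell $x$ is the Gaussian kernel sum
$\rho(x) = \sum_{y} \exp(-d(x,y)^2 / 2\sigma^2)$ over all cells
(including $x$ itself, so $\rho \ge 1$), and the pseudo-potential is
$\tilde E(x) = -\log \rho(x)$. The bandwidth $\sigma$ is the 0.02
quantile of all pairwise distances by default (`deriveSigma`), using
linear interpolation between order statistics (R's default type-7
quantile); a small quantile keeps $\rho$ local. Distances are
Euclidean, computed in an optional PCA subspace
(`preprocessCells(reduceTo = ...)`): with isotropic per-gene noise of
standard deviation $s$ in $n$ genes, every small distance acquires a
floor of about $s\sqrt{2n}$, which blurs ring geometry; projecting to
the top principal components removes most of that floor while
preserving the trajectory, and is the configuration used throughout
the package's own tests.

Backbone growth starts at the cell with the globally minimal
pseudo-potential (or a user-chosen cell) and repeats three steps
breadth-first:

* **Adaptive step** (`adaptiveStep`): the super-ring radius is the
  smallest $r \ge 3\sigma$ on the geometric grid $3\sigma \cdot 1.1^k$
  whose annulus $[r - w, r + w]$ (half-width $w = \sigma$) holds at
  least 10 cells. If no radius within the data extent qualifies, the
  branch has reached the data boundary and terminates.
* **Well search on the ring** (`findWellsOnRing`): the decision-graph
  statistic $\delta$ is computed on the annulus members ($\delta$ =
  distance to the nearest member with lower $\tilde E$; for the
  member with minimal $\tilde E$, the largest distance to any other
  member; ties in $\tilde E$ break by cell index). Candidates need
  $\delta \ge r/2$ and, under the default `"support"` filter, at
  least 5 members within $r/2$ — a local-support requirement that
  rejects isolated outliers. An alternative `"median"` filter
  (candidate below the ring's median $\tilde E$) is available but not
  the default: when one branch is much sparser than its sibling
  (e.g. post-branch arms carry half the trunk's density), the sparser
  branch's genuine well sits above the ring median and would be
  discarded. Finally one well is kept per *density-connected piece*
  of the ring: members are single-linkage clustered at cutoff $w$,
  and only the deepest candidate of each cluster survives. A plain
  distance threshold between candidates is not used because wells
  drift toward the annulus' inner edge near a branch point, where two
  genuinely distinct arms can approach each other to within a step.
* **Linking with exclusion**: surviving wells become child nodes of
  the ring center unless they lie within one half-width of the
  *polyline* of the existing tree (nodes and edges). That tube
  exclusion removes the well re-found on the reverse search direction
  — which always hugs already-covered territory — without blocking
  sibling branches, which diverge from the polyline. A plain
  node-distance exclusion fails in both directions: at one step it
  starves siblings, at a fraction of a step it misses reverse wells
  that fall mid-gap between consecutive nodes.

Two post-passes clean the raw tree. *Spur pruning* iteratively
removes leaf nodes within 1.5 half-widths of the remaining polyline;
such spurs are duplicate tracks laid down when two frontier rings race
into the same region, whereas genuine trajectory ends sit a full step
away from everything else. *Branch-node contraction* merges adjacent
nodes that both have degree ≥ 3 and lie closer than one step length:
two fate-decision points cannot be resolved below the search
resolution, so a trifurcation initially found as two tight
bifurcations becomes a single degree-4 node. Both passes can be
disabled (`pruneFactor = 0`, `contractFactor = 0`).

The default backbone path contains no random number generation — it is
deterministic given the matrix and the configuration.

# Projection and pseudotime

Each cell projects to the closest point over all tree edges
(perpendicular foot clamped to segment ends; ties go to the lower edge
id). The root is the tree node minimizing total distance to
user-supplied root-candidate cells, falling back to the growth start.
Pseudotime is the path length from the root to the projection, divided
by the maximum over cells, so $\tau \in [0, 1]$. Maximal unbranched
edge chains — enumerated root-first with children in ascending node id
— define branch labels; one chain is one candidate cell type.

# The random walk and the landscape potential

Transitions between cells are modeled as a random walker on a directed
graph. The edge $\alpha \to \beta$ carries weight
$W_{\alpha\to\beta} = W_0 \, e^{-\chi(\tau_\alpha - \tau_\beta)}$ with
$\chi = 30$ by default, so moves forward in pseudotime are
exponentially favored. The support is restricted to the symmetrized
k-nearest-neighbor graph (k = 10): without the restriction the weight
rule assigns factors up to $e^{\chi}$ to arbitrarily distant cells and
destroys locality (a dense all-pairs variant remains available with
`kNeighbors = NULL`). The walker moves with conditional probability
$p_{\beta\to\alpha} = W_{\beta\to\alpha} / \sum_{\alpha'}
W_{\beta\to\alpha'}$ — independent of $W_0$, and rows sum to one by
construction.

The stationary visit distribution solves the teleported fixed point
$$p_\alpha = (1-\varepsilon)\sum_\beta p_\beta\, p_{\beta\to\alpha}
  + \varepsilon\, v_\alpha, \qquad
  v_\alpha = \frac{\sum_\beta W_{\alpha\to\beta}}
                  {\sum_{\alpha,\beta} W_{\beta\to\alpha}},$$
with $\varepsilon = 0.01$; teleportation makes the solution unique and
strictly positive. The teleportation mass $v$ uses each cell's total
*out*-link weight as written above (the package's default); a variant
proportional to *in*-link weight is available via
`teleport = "in-weight"`, since the two readings are both defensible
and differ only through the teleportation term. Power iteration from
the uniform vector runs to an L1 residual of 1e-10 (cap 1e4
iterations; the iteration preserves the simplex, so $\sum p_\alpha = 1$
throughout). The landscape potential is $E_\alpha = -\log p_\alpha$.

The pseudo-potential and the potential measure different things: the
former is density only, the latter inherits the direction of
development through $\chi$. On data where early progenitor cells are
*denser* than late cells, early cells have the lower pseudo-potential
but the higher landscape potential — the package's test suite
constructs exactly this contrast with the `"early-dense"` generator
profile.

For visualization (`buildLandscapeSurface`), cells are embedded in 2-D
by deterministic PCA (component signs fixed by making the
largest-magnitude loading positive; a user-supplied embedding is also
accepted — no t-SNE backend is bundled, keeping the default
reproducible). Each point of a regular grid (default 200 × 200 over
the embedding's bounding box) takes the potential of its nearest
embedded cell, then the grid is convolved with a separable Gaussian
kernel (default bandwidth 2 grid cells, truncated at 4 bandwidths and
renormalized at the borders; bandwidth 0 is the exact
nearest-neighbor surface). The backbone is pushed through the same
embedding as an overlay.

# Cell types, subtypes, and fate probabilities

Every maximal unbranched chain is one cell type. Within a type,
potential wells along pseudotime define subtypes: per-cell potentials
are smoothed against $\tau$ with a moving average (window 5% of the
branch's $\tau$ range), local minima separated by barriers of at least
0.1 natural-log units (measured from the higher flanking minimum to
the intervening maximum) are wells, and basin boundaries sit at the
maxima between surviving minima. Branches with fewer than 10 cells
stay a single subtype. Both thresholds are configuration parameters
because well shapes depend on the dataset; the defaults are a
conservative reading ("a barrier below 10% of an e-fold of visit
probability is not a barrier").

Link visit rates are $q_{\alpha\to\beta} = p_\alpha\,
p_{\alpha\to\beta}$; summed over all links they equal one exactly.
For types $i \ne j$, the transition probability aggregates
$q_{i\curvearrowright j} = \sum_{\alpha\in i,\,\beta\in j}
q_{\alpha\to\beta}$, the exit probability sums all links leaving $i$,
and the fate probability is $\text{fate}_i = 1 - q_{i\curvearrowright}$.
With this index set, $q_{i\curvearrowright} = \sum_{j\ne i}
q_{i\curvearrowright j}$ holds as an exact identity, which is what
makes the fate definition consistent; an alternative
"everything-except-$j$" aggregation breaks the identity and is kept
only behind `printedIndexSet = TRUE` for comparison. On data with a
forward pseudotime gradient and $\chi = 30$, transitions from the root
type into each downstream type exceed their reverse counterparts — the
directionality one expects of differentiation.

# Windowed gene networks and the critical-transition index

Windows of equal width tile $[0, 1]$ with 50% overlap by default;
with `perBranch = TRUE` the tiling is intersected with branch scopes
(chains from the root to the first branch point jointly form the
"pre-branch" scope; every other chain is windowed separately), so no
window mixes post-branch branches. Windows under 30 cells merge with
their neighbor.

Per window, a regulator → target importance matrix is inferred with a
randomized regression-tree ensemble (an Extra-Trees variant written in
C++): for each target gene, 500 trees by default, square-root feature
subsampling, one uniform random cut point per candidate feature, and
importance equal to the total variance reduction a regulator achieves,
averaged over trees. Targets are scaled to unit variance so
importances are comparable across targets. All-zero genes are removed
first; constant genes get zero importance with a warning. A seed is
mandatory and results are bit-reproducible given it.

The neighborhood of a core gene ranks candidates by their symmetrized
importance with the core (ties: absolute correlation, then gene id)
and admits them greedily while their mean absolute Pearson correlation
with the already-admitted members (core included) stays at or above
0.3, up to 6 partners — a module of genes tied to the core and to each
other.

Two window-level indices summarize coordination: the gene correlation
degree (mean absolute Pearson correlation over non-constant gene
pairs, computed across the window's cells) and the cell correlation
degree (mean signed Pearson correlation over cell pairs, computed
across the panel genes). Their ratio is reported when the cell degree
exceeds 0.05 (below that floor the ratio is dominated by noise and
flagged undefined). Near a fate transition, cell-to-cell correlation
collapses faster than gene-to-gene correlation — heterogeneity grows
as the attracting basin flattens — so the ratio rises to a maximum at
the transition. The package's generator for this phenomenon
(`simulateRegulatoryPanel` with pseudotime-dependent profiles) weakens
regulator-target coupling mildly and grows per-gene noise strongly
toward a designed transition at $\tau = 0.5$: with independent
per-gene noise of scale $s$, gene correlations fall like $1/s$ while
cell correlations fall like $1/s^2$, reproducing the peaked ratio.
Fixed per-gene baseline offsets give cells a shared expression profile
without which the cell correlation degree would be identically near
zero.

# Bursting kinetics by Gamma maximum likelihood

Nonzero expression values of a gene within a window are modeled as
Gamma draws with shape $a$ (mean burst frequency, bursts per cell
cycle) and scale $b$ (mean burst size, transcripts per burst). Zeros
are excluded: the Gamma has continuous positive support and zeros in
droplet-style data are dominated by technical dropout. The MLE solves
$\log a - \psi(a) = \log \bar x - \overline{\log x}$ by Newton
iteration on $a$, started from the method-of-moments value
$\bar x^2 / s^2$ and safeguarded by a shrinking bracket (the left side
is strictly decreasing in $a$, so the bracket always contains the
root; a bisection step replaces any Newton step that leaves it).
Convergence requires successive iterates to agree within 1e-10
(relative); $b = \bar x / a$ then enforces the first-moment identity
$\hat a \hat b = \bar x$ exactly. Fewer than 20 nonzero observations
give a "not estimable" record; zero sample variance flags the
degenerate $a \to \infty$ limit. Fits use the preprocessed,
non-log-transformed values by default — log transformation would
change the distributional family.

Each converged fit is classified in the (frequency, size) plane:
"high frequency" means $\hat a > 0.33$ and "small burst" means
$\hat b < 200$ transcripts; a gene is *bursty* unless it is
high-frequency/small-burst. The fixed thresholds follow the reference
values quoted for this classification; a `"dataset-mean"` mode uses
the means of the window's fitted values instead, since both readings
of the reference lines are defensible. Window summaries average
$\hat a$ and $\hat b$ over converged fits, report the mean expression
level with zeros included, and carry branch scope so pre- and
post-branch trends stay separable.

# Synthetic data: what it does and does not establish

The generators are pure functions of their arguments including the
seed, and always return machine-readable ground truth.

* `simulateBranchingTrajectory`: piecewise-linear skeletons in a 2-D
  latent plane — linear (length 10), single bifurcation (trunk 5,
  arms 5 at ±45°), double bifurcation (second split at ±45° off one
  arm), trifurcation (arms at -70°/0°/+70°; adjacent arms then stay
  separated by more than one ring step at the default geometry) —
  embedded isometrically into gene space by a seeded random
  orthonormal map, shifted by positive per-gene offsets, plus
  isotropic Gaussian noise (default sd 0.05 per gene, a regime where
  the 10-component PCA step recovers the latent geometry). Latent
  times are uniform, or Beta(1, 2) under `"early-dense"`.
* `simulateBurstyExpression`: per-cell, per-gene Gamma draws with
  shape and scale curves $a(\tau), b(\tau)$, plus Bernoulli dropout.
* `simulateRegulatoryPanel`: standard-normal regulators, linear
  targets with pseudotime-dependent coupling and noise, independent
  decoys, fixed per-gene baselines.

A green test on these generators establishes that the algorithms
recover the structure they were designed for under Gaussian noise and
smooth geometry. It does not establish performance on real single-cell
counts: the generators have no mean-variance relation, no
library-size variation, no batch structure, and no UMI discreteness
beyond the Gamma + dropout model; branch angles are generous; and
densities vary smoothly. Results on real data additionally depend on
pre-processing choices that are deliberately exposed rather than
fixed.

# Default parameters at a glance

| parameter | default | units / meaning |
|---|---|---|
| `sigmaQuantile` | 0.02 | quantile of pairwise distances defining the kernel bandwidth |
| `baseRadiusFactor` | 3 | ring base radius, in bandwidths |
| `halfWidthFactor` | 1 | annulus half-width, in bandwidths |
| `minRingCells` | 10 | minimum annulus occupancy |
| `deltaMinFactor` | 0.5 | well threshold on delta, in ring radii |
| `supportMin` | 5 | members within r/2 required of a well |
| `excludeFactor` | 1 | tube-exclusion distance, in half-widths |
| `mergeFactor` | 1 | connectivity-merge cutoff, in half-widths |
| `pruneFactor` | 1.5 | spur-pruning distance, in half-widths |
| `contractFactor` | 1 | branch-node contraction, in step lengths |
| `chi` | 30 | pseudotime sensitivity of edge weights |
| `kNeighbors` | 10 | random-walk support |
| `epsilon` | 0.01 | teleportation rate |
| `nWindows`, `overlapFraction` | 10, 0.5 | pseudotime tiling |
| `nTrees` | 500 | ensemble size per GRN target |
| `kPartners`, `mutualThreshold` | 6, 0.3 | neighborhood extraction |
| `minObs` | 20 | nonzero observations per Gamma fit |
| `bfThreshold`, `bsThreshold` | 0.33, 200 | bursting quadrant lines |

# Known limitations

* Trajectories are assumed loop-free; cyclic processes (e.g. cell
  cycle) violate the tree model.
* Fewer than ~100 cells make density-based well finding unreliable;
  `growBackboneTree` refuses such inputs.
* Branches diverging at shallow angles (below roughly 45°) or
  separated by less than the ring half-width may merge; the search
  resolution is set by the kernel bandwidth.
* The landscape potential depends on the pseudotime through $\chi$;
  a poor ordering propagates into every downstream module.
* Gamma fits on log-transformed or heavily normalized values estimate
  parameters of the transformed distribution, not burst kinetics.
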