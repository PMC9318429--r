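---
title: "Principal amalgamation analysis: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal amalgamation analysis: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paar)
```

## The problem

Relative-abundance microbiome tables are compositional (each sample is a
point on the simplex), extremely sparse, and high dimensional, and the taxa
carry a taxonomic tree. Ordination methods such as PCA or PCoA compress such
data into abstract axes that are hard to read back in terms of taxa, and
log-ratio approaches need arbitrary zero replacement. Amalgamation — summing
disjoint groups of components — is the one dimension-reduction operation that
keeps the result a composition over nameable groups of taxa, with no
transformation and no zero handling.

Principal amalgamation analysis (PAA) makes amalgamation systematic: choose a
binary loading matrix $R \in M_0(k,p)$ (columns sum to one, so $R$ encodes a
partition of the $p$ taxa into $k$ groups) minimizing an information loss
$L(R; X)$, and call the amalgamated columns of $XR^\top$ the *principal
compositions*. Exact minimization over $M_0(k,p)$ is combinatorial and
infeasible beyond toy sizes, so the package implements a hierarchical greedy
algorithm (HPAA): starting from the $p$ original taxa, at each of the $p-1$
steps the single pair of current columns whose merge loses the least
information is summed, producing the entire path of nested partitions at
once. Any $k$ is then a horizontal cut of that path (`cut(path, k)`).

## Loss functions

Information is measured by a diversity index, chosen by what the analysis
must preserve.

**Within-sample ($\alpha$) losses.** The loss is the decrease in the total
index $\sum_i \alpha(x_i)$.

* `sdi` — Simpson's diversity index $1 - \sum_j x_{ij}^2$. The step
  criterion reduces to the inner product of the two candidate columns; the
  realized drop in total SDI is exactly twice that inner product, which the
  test suite verifies against from-scratch recomputation. Because only two
  columns change per merge, the Gram matrix of the current data is cached
  and updated in $O(m)$ per step; a full path at $n = 100$, $p = 300$ runs
  in well under a second.
* `swi` — Shannon–Wiener index $-\sum_j x_{ij}\log x_{ij}$ (natural log).
  Zeros are handled by the continuity convention $0\log 0 = 0$, under which
  the step cost $(a+b)\log(a+b) - a\log a - b\log b$ is well defined and
  non-negative on sparse data with no replacement scheme. Users who want
  classical zero replacement can pass `pseudocount`: zeros become
  $\varepsilon$ and rows are re-closed before the path is fitted. We chose
  the limit convention as the default because it is the unique choice that
  keeps the index continuous at the boundary of the simplex and therefore
  keeps the greedy criterion stable on data with 40%+ zeros.

**Between-sample ($\beta$) losses.** The loss is the squared distortion of
the pairwise distance matrix, $\sum_{i<i'}\{\beta(x_i,x_{i'}) -
\beta(Rx_i,Rx_{i'})\}^2$.

* `bc` — Bray–Curtis, which on compositions equals half the Manhattan
  distance, $1 - \sum_j \min(x_{ij}, x_{i'j})$.
* `wuf` — weighted UniFrac,
  $\sum_j l_j\,\lvert x_{ij}-x_{i'j}\rvert \,/\, \sum_j L_j\,(x_{ij}+x_{i'j})$,
  where $l_j$ is the branch length of the leaf carrying taxon $j$ and $L_j$
  its root-to-leaf path length, both taken from the current reduced tree.

Each greedy step scores a candidate pair on the *current* matrix
$X_{t-1}$ (exactly the stepwise criterion), while the cumulative loss
reported in `path$steps` and drawn in the scree plot is always measured
against the *original* data: for $\alpha$ losses as the percentage of the
original total diversity lost, for $\beta$ losses as the percentage of the
original squared distance mass distorted. Both are 0 at $k = p$ and 100 at
$k = 1$.

## Taxonomic guidance and tree reduction

Three hierarchy modes control the active set of candidate pairs:

* `none` — all $\binom{m}{2}$ pairs;
* `weak` — only pairs sharing their lowest multi-child ancestor $A^*$ in the
  current reduced tree (unary chains above a leaf are skipped, so taxa
  classified at different ranks can still be siblings in the $A^*$ sense);
* `strong` — weak pairs whose two members additionally sit at the current
  maximum leaf depth, so the lowest rank is always consumed first.

Trees may be non-complete (leaves at different depths) and may contain unary
rank nodes; both arise naturally from lineage strings of partially
classified taxa and both are preserved by the lineage parser and the Newick
reader.

After every merge the tree is reduced in step with the data. The definition
of weighted UniFrac fixes what the branch lengths mean but not how they
update when taxa merge, so the following are package design choices, fixed
once:

* the merged leaf attaches below the pair's shared $A^*$ when one exists
  (guaranteed in weak/strong modes) and below their lowest common ancestor
  otherwise;
* its edge length is 1 on unit-length (rank-based) taxonomies, and the
  minimum of the two replaced edge lengths on trees with real branch
  lengths — the conservative choice that cannot inflate the new branch
  beyond either parent branch;
* internal nodes left childless are deleted and nodes left with a single
  child are collapsed into that child with edge lengths summed, so
  root-to-leaf path lengths of untouched taxa are invariant (a tested
  property). The collapse is what lets a last remaining taxon at some rank
  rise to the next rank.

In strong mode a lone deepest leaf can be left without any eligible partner.
The runner then collapses the unary chains above the current deepest leaves
(raising the stranded taxon one rank) and retries; if an eligible pair still
does not exist, that step falls back to the weak rule restricted to ancestor
groups containing a deepest taxon. One can show the collapse loop always
terminates: if the deepest leaf is a direct child of its multi-child
ancestor, either a same-depth sibling exists (a strong pair) or a deeper
leaf exists elsewhere (contradiction with it being deepest).

Ties in the step criterion are broken by the lexicographically smallest pair
of current column indices. The algorithm contains no randomness, so a path
is bitwise reproducible; ties occur on symmetric or zero-overlap data, and
the deterministic rule is also what makes the planted-structure recovery
experiment (below) exact.

## What is and is not monotone

Along any path, total Simpson and Shannon diversity are non-increasing, and
every pairwise Bray–Curtis distance is non-increasing at every step; these
follow from superadditivity inequalities of the respective measures and the
test suite asserts them on every fitted path. Two plausible-looking stronger
statements are **false**, and the package deliberately does not promise
them:

* *Pairwise weighted UniFrac is not monotone under amalgamation.* On the
  3-leaf tree `(a:1,(b:1,c:1):1)` with $x = (1,0,0)$ and $y = (0,\tfrac12,
  \tfrac12)$, merging $(b, c)$ raises WUF from $2/3$ to $1$: merged leaves
  rise toward the root, the normalizing denominator $\sum_j L_j(x_j+y_j)$
  shrinks, and the ratio can grow. On random sparse data over half the
  steps raise at least one pairwise WUF distance. Consequently the
  cumulative WUF distortion curve need not be monotone either; the `wuf`
  loss still greedily minimizes the stepwise distortion, which is always
  non-negative.
* *Loss curves of nested hierarchy modes need not be ordered at every
  cut.* The unconstrained active set contains the weak one, which contains
  the strong one, so the constrained mode can never win *a single step from
  the same state*; but the greedy paths diverge, and on roughly one random
  instance in seven the weak (or strong) path reaches some $k$ with
  strictly lower cumulative SDI loss than the less constrained mode, by up
  to a few percentage points. The scree plot is the honest summary: the
  curves are usually ordered and always close at large $k$, but the
  ordering is a tendency, not an invariant.

## Synthetic data generator

`synth_spec()` / `simulate_taxonomy()` / `simulate_compositions()` generate
the fixtures every test runs on. The defaults emulate a genus-level gut
profile of the kind the method targets: 50 samples, 60 taxa, a depth-6
taxonomy grown with 2–4 children per split and a 15% chance of unary rank
nodes (non-complete classification), per-sample Dirichlet weights over 5
planted taxon groups with Dirichlet splits within groups, and independent
zero masking at rate 0.4 followed by row re-closure — matching the roughly
40% zero fraction typical of genus-level tables. The realized zero fraction
lands within half a percentage point of the target at these sizes.

The generator is honest about what it does not emulate: no library-size or
count-level noise (entries are exact proportions, not rarefied counts), no
overdispersion beyond the Dirichlet, no phylogenetic signal in the
abundances (group membership, not tree distance, drives correlation), and
no longitudinal structure. Passing tests therefore demonstrate algorithmic
correctness and scaling, not biological validity on real sequencing runs.

`simulate_compositions(..., disjoint_support = TRUE)` produces the sharper
design used for structure recovery: each sample carries mass on exactly one
taxon per planted group, assigned by a shuffled round-robin so every taxon
is expressed somewhere (this needs `n_samples >=` the largest group). Taxa
within a group then never co-occur, so every within-group merge is free
under the SDI criterion while merges across completed groups are not, and
unconstrained SDI amalgamation recovers the planted partition at $k = g$
exactly (adjusted Rand index 1), which the acceptance suite checks over 40
seeds for $g \in \{3, 5, 8\}$.

## Visualization

* **Dendrogram** (`plot_dendrogram`) — merge heights are cumulative
  percentage loss; for $\alpha$ losses the axis is log-scaled by default
  (zero heights are floored at half the smallest positive height; a fully
  degenerate zero-loss path falls back to a linear axis with a warning).
  Red dashed guides mark the cuts at which the data could be aggregated to
  a named rank (computed from lineage metadata), and stacked per-rank color
  bars run under the leaves. In weak/strong modes every taxonomy clade is
  completed before it merges outward, so each rank category occupies a
  contiguous block of leaves — a tested property.
* **Scree plot** (`plot_scree`) — cumulative percentage loss against $k$,
  one curve per hierarchy mode, for choosing $k$.
* **Ordination** (`ordinate` + `plot_ordination`) — 2-D NMDS (Bray–Curtis,
  monotone stress-1 via `vegan::metaMDS`, 16 random starts, fixed recorded
  seed) of the original samples pooled with their principal compositions,
  each pair enclosed by its smallest covering circle; radii visualize
  per-sample distortion. Because original samples live in $p$ dimensions
  and scores in $k$, the scores are first lifted back to taxon space:
  each group's mass is split over its member taxa proportionally to their
  mean abundance in the original data (equal split for groups with no mass
  anywhere). This lift is the minimal construction making cross-set
  Bray–Curtis well defined; proportional weights make $k = p$ an exact
  identity, so identity cuts yield coincident point pairs. Rows that are
  bitwise identical are embedded at identical coordinates (they are
  indistinguishable at zero dissimilarity), which keeps that exactness
  through the NMDS stage. NMDS non-convergence triggers one retry with
  doubled starts and is flagged in the result.

## Numerical choices and degenerate inputs

* Row sums are validated to $10^{-8}$ on input; amalgamation conserves mass
  to machine precision and score matrices are re-validated at every cut.
* Step costs are clamped at zero against $-10^{-17}$-scale float noise so
  cumulative $\alpha$ curves are exactly non-decreasing.
* All-zero taxon columns are legal; they merge at zero cost wherever the
  tie-break places them.
* Compositions with all rows identical give a degenerate $\beta$ loss
  (denominator 0); the percentage curve is reported as 0 rather than NaN.
* `p = 1` inputs and single-leaf trees are rejected with explicit errors,
  as are weak/strong runs without a taxonomy and `wuf` without a tree.
* Problem sizes in the test suite (instances up to $p = 20$ for exhaustive
  oracles, $n = 100$, $p = 300$ for the scaling check, 120 recovery runs)
  keep the full suite around half a minute on one CPU.

## Limitations

Greedy HPAA approximates, and does not solve, the exact PAA program; no
optimality gap is claimed at any $k$. The weighted UniFrac branch-length
update rule for merged taxa is a documented convention, not uniquely
determined by the distance's definition, so WUF paths from other
implementations with other conventions may differ. NMDS coordinates are
only defined up to rotation and the stress surface is multimodal; fixing
the seed makes figures reproducible, not canonical.
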