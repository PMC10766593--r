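---
title: "Aligning replicate mixed-membership clusterings: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning replicate mixed-membership clusterings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modalign)
```

## The problem

Programs such as Structure and Admixture are run many times per dataset,
both across numbers of clusters K and as replicates at fixed K. Replicate
output disagrees for two reasons with very different meanings: arbitrary
cluster numbering (label switching) and convergence to genuinely
different co-clustering patterns (multimodality). `modalign` separates
the two: it aligns cluster labels optimally, groups replicates into
modes, summarizes each mode, and aligns modes across K.

## Dissimilarity model

All computation rests on one two-level dissimilarity. Between cluster
columns, `cluster_cost()` is the scaled squared difference
$C(q_{\cdot i}, p_{\cdot j}) = \frac{1}{2N}\sum_\ell (q_{\ell i} -
p_{\ell j})^2$, which lies in $[0,1]$ because memberships do. Between
replicates under a mapping $\alpha$, `replicate_dissimilarity()` sums the
costs along the mapping. Two facts shape everything downstream:

* for equal K and any permutation $\alpha$, each individual's squared
  contribution is at most 2, so $D \le 1$, with hard assignments that
  disagree everywhere attaining 1 exactly;
* $D = (1 - G')^2$, tying $D$ to the classic Frobenius similarity $G'$.
  We take the square-root form $G' = 1 - \|Q - P\|_F / \sqrt{2N}$; it is
  the only reading under which that identity is exact (enforced to
  `1e-10` by test) and it matches $G'$'s historical definition.

For K1 > K2 the mapping is many-to-one and surjective, and $D$ can exceed
1 (three hard clusters collapsed onto two can charge 3 per individual).
A Jaccard-flavored cluster similarity restricted to the support of each
column pair is also provided, but only for comparison with other tools'
scores — it cannot reach 0 (its floor is $1 - 1/\sqrt{2}$ when all
memberships are positive) and is never used as an objective.

## Exact alignment

`solve_alignment_ilp()` minimizes $\sum_{ij} W_{ij} C_{ij}$ over binary
indicator matrices with unit row sums and column sums at least 1. The
cluster counts this problem sees are small — published analyses rarely
exceed a few tens — so we solve the binary program exactly with a
depth-first branch-and-bound written for this constraint system. The
lower bound adds, to the cost so far, each remaining row's cheapest
entry plus, for every still-uncovered target column, the cheapest
surcharge any remaining row would pay to cover it; this bound is
admissible because covering rows for distinct targets are necessarily
distinct. No LP relaxation or rounding is involved, and every returned
indicator is re-checked against the constraints and its objective.

Co-optimal mappings exist (exactly tied costs arise with symmetric or
rounded inputs), and the tie-break is part of the contract: after the
optimal cost is known, $\alpha(1), \alpha(2), \ldots$ are greedily fixed
to the smallest target preserving optimality within `1e-9`, yielding the
lexicographically smallest optimal mapping regardless of search order.
`brute_force_alignment()` enumerates every surjection (guarded at
$10^6$) with the same tie definition and serves as the independent
oracle: the suite cross-checks the two on hundreds of random instances,
tied and untied. We deliberately run the same solver for equal K rather
than dispatching to a dedicated assignment algorithm; the problems are
tiny and a single code path keeps tie-breaking trivially consistent.

## Modes

`build_replicate_graph()` aligns all $R_K(R_K-1)/2$ pairs and rescales
dissimilarities into weights $u_{ij} = (D_{max} - D_{ij}) / (D_{max} -
D_{min})$. When $D_{max} = D_{min}$ — identical replicates, or any
two-replicate group — every pair is equally similar and all off-diagonal
weights are set to 1; any other convention would impose structure that
is not there.

Splitting is gated behind a test of the null of no community structure.
The literature test this follows compares extreme eigenvalues of two
transforms of the weight matrix against fixed rejection intervals whose
constants we do not reproduce; instead `test_community_structure()`
computes the same statistics — the extreme eigenvalues of the
off-diagonal-centered matrix and of its degree-normalized counterpart —
and calibrates them against a Monte-Carlo null built by permuting the
off-diagonal entries (199 draws, seeded), rejecting at $p = 0.01$. The
gate is pluggable (`test_fn`) so an interval-based variant can be
substituted without touching callers. With 199 draws the smallest
attainable p-value is 0.005, so rejection at 0.01 requires the observed
statistic to be more extreme than all but at most one permutation.

When the gate rejects, `detect_modes()` runs Louvain on the full
weighted graph — no edge thresholding — with a resolution parameter
(default 1; larger values give more, smaller modes) and a seed that
fixes the sweep order, making partitions reproducible. Modes are ordered
by decreasing size, then decreasing within-mode similarity, then
smallest member id.

`build_consensus()` brings each member into a common cluster frame and
averages. The frame is the mode's *representative* — the member with the
largest within-mode weight sum — because the pairwise alignments to it
already exist (no new solves) and it is the mode's most central point;
whether the original method anchors on the representative or an
arbitrary member is not specified, and this is our choice. Averaging
row-stochastic matrices keeps rows stochastic, so the mean consensus is
itself a valid membership matrix. No iterative re-alignment to the
running mean is attempted.

## Across K and layout

Layers are the distinct K values sorted decreasingly; only consecutive
entries of that list are aligned (a gap such as K = 5 next to K = 3 is
allowed for the direct method and simply labeled as a gap). The direct
method aligns mean consensus matrices many-to-one and weights edges by
$\mu = 1 - D$; $\mu < 0$ is possible for unequal K but requires grossly
mismatched clusters, so it is kept and warned about, never clamped. The
merge method, for consecutive K only, tries all $\binom{K+1}{2}$ column
merges of the larger-K mode and keeps the best equal-K alignment (ties:
lexicographically smallest merged pair). The across-K score sums the two
collided columns of the (K+1)-mode and takes $G'$ against the K-mode; by
construction the merge winner can never score below the direct alignment
on this quantity, a property the suite asserts on random fixtures.

Each adjacent layer pair's maximum-$\mu$ edge is its *anchor* (ties:
larger combined mode size, then smallest indices). Colors start at the
largest-K anchor and propagate: within a layer, every mode is aligned to
the layer anchor; across layers, each smaller-K cluster inherits the
color of the smallest-slot source cluster mapped onto it. The
composition gives every mode one final display permutation, so matched
clusters share colors across the whole figure. Rendering draws stacked
bars per individual, inter-layer edges darkened linearly in $\mu$
(clipped to $[0,1]$ for drawing only) and labeled with the optimal cost
to 3 decimals, plus per-mode histograms of within-mode dissimilarities.
No quantity is computed at plot time.

## Synthetic data: what it does and does not emulate

`generate_collection()` plants everything the pipeline is supposed to
recover: per mode a base matrix with symmetric-Dirichlet rows
(concentration 1 by default — uniform on the simplex, a neutral admixed
profile; explicit bases can be supplied when a test needs guaranteed
separation), per replicate additive uniform noise of half-width
`noise_scale` (default 0.05, comparable to run-to-run MCMC variation)
clipped at zero and renormalized, and a uniformly random planted label
permutation. This emulates the statistical structure the method assumes
— replicates as noisy, relabeled copies of mode centers — and nothing
more: no linkage between individuals, no genotype likelihoods, no
convergence failures, no correlation between noise and membership
magnitude. Passing recovery tests on these fixtures therefore
demonstrates correctness of the alignment and detection machinery, not
robustness to every pathology of real MCMC output.

## Numerical choices and problem sizes

Rows are accepted when they sum to 1 within $10^{-4}$ (published Q files
round to about six decimals) and renormalized exactly; grosser
violations are errors. Outputs are written at six decimals. Cost
matrices are computed via the expanded cross-product form and clamped at
zero to absorb the $-10^{-17}$-scale negatives the expansion can produce
for identical columns. Alignment tie tolerance is `1e-9`; the
constraint re-check uses the same. The test suite exercises the solver
against the exhaustive oracle on 500 random instances (K up to 5), the
bound sweep on 10,000 random pairs (N up to 50, K up to 6, all
permutations per pair), planted-permutation recovery on 100 cases (N up
to 100, K up to 8), and planted two-mode recovery across 50 seeds with a
between/within cost ratio verified above 5 — sizes chosen to exercise
every code path at full strength while keeping the suite fast on a
single core.

## Known limitations

* The branch-and-bound is exponential in the worst case; it is intended
  for the cluster counts mixed-membership analyses actually use (K up to
  a few tens), not for hundreds of clusters.
* The community-structure gate is a calibrated stand-in contract, not a
  reproduction of the cited interval test's unpublished constants; its
  permutation null conditions on the observed weight values.
* Only adjacent layers of the sorted K list are aligned; no transitive
  alignment between non-adjacent layers is computed.
* Louvain partitions, while seeded and reproducible, are heuristic; a
  different seed can occasionally split borderline modes differently.
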