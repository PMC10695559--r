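---
title: "Methods: from c-fos counts to functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from c-fos counts to functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`fosnet` treats per-animal counts of c-fos expressing cells as a snapshot of
regional activation during a behavioral epoch. For a group of animals, the
functional coupling of two regions is the across-animal Pearson correlation
of their counts; the group's 12×12 matrix of pairwise correlations (diagonal
zeroed by convention) is the object everything downstream is built from.
The implicit assumptions are worth stating plainly:

* **Animals are the sampling unit.** Each group's matrix is estimated from
  its animals only (n ≥ 3 enforced, n = 8 typical). At n = 8 a single r
  value has a standard error of roughly 0.35 near zero — the pipeline's
  comparisons therefore work with *distributions* of r values, never a
  single pair.
* **Matrix entries are treated as samples.** Between-group tests
  (Kruskal–Wallis, then pairwise Mann–Whitney when the omnibus p < 0.05)
  treat the 66 upper-triangle entries as independent observations. They are
  not — they share animals — so these tests are descriptive conventions of
  the field, not strictly valid inference. The package reproduces the
  convention and documents it rather than replacing it.
* **Raw r, no Fisher z.** Group comparisons are on the r scale, unadjusted
  pairwise p values, matching field practice.

## Thresholding

A single cutoff — the mean plus one sample SD (n−1 denominator) of the
upper-triangle values pooled across *all* groups — is applied to every
group's matrix; an edge is retained when its r **strictly** exceeds the
cutoff. Design choices here:

* One pooled threshold, not per-group thresholds, so that network
  differences reflect the data rather than per-group calibration.
* Signed r is pooled and compared; negative correlations can never pass a
  positive cutoff. Absolute values play no role in network construction.
* Strictness at the boundary is measure-zero on real data; it is fixed for
  determinism.
* Isolated nodes remain in the node set: a region whose every correlation
  fell below threshold is a finding (the strong-memory amygdala motif), not
  a missing value.

## Two path conventions, deliberately

Betweenness uses **unweighted** geodesics (shortest = fewest edges), with
fractional credit `σ_st(v)/σ_st` when several geodesics tie — the standard
resolution when the source definition is silent about ties. Efficiency uses
**weighted** distances with edge length `1/r`, so strong correlations are
short functional hops. Nodal efficiency is the mean inverse distance to all
other nodes with `1/∞ = 0` for unreachable pairs (never NA, never dropped);
global efficiency is the plain mean of nodal efficiencies. Both conventions
are verified in the test suite against independent oracles (exhaustive
geodesic enumeration; all-pairs relaxation) to 1e−12 on random graphs.

## The small-world null

Each memory network is compared with 1000 Watts–Strogatz graphs on the same
12 nodes:

* **k** (even lattice degree) is the network's mean degree rounded to the
  nearest even integer, ties upward — the closest parameter-free density
  match the WS family allows.
* **p** (rewiring probability) is tuned so the *mean* clustering coefficient
  of the ensemble (estimated from the same number of draws) is within 0.02
  of the memory network's clustering; the search starts at the analytic
  approximation `C(p) ≈ C(0)(1−p)³`, `C(0) = 3(k−2)/(4(k−1))`, and refines
  by bisection. The analytic formula ignores the random-graph clustering
  floor (≈ k/n), which matters at n = 12: targets below the floor end in a
  convergence warning at best effort.
* **Null edge weights are 1.** The comparison weighs a 1/r-weighted memory
  network against unit-weight nulls; since retained r values lie near 1 the
  mismatch is modest, but it biases the memory side downward — a memory
  network with mean retained r of 0.75 loses ~25% efficiency relative to a
  topologically identical unit-weight graph. This is the only
  parameter-free choice and is stated prominently rather than hidden.
* **The interval** is the 2.5th–97.5th percentile (linear-interpolation,
  type-7 quantiles) of the per-replicate differences
  (null − memory). A percentile interval was chosen over a normal-theory one
  because the published intervals of this analysis style are asymmetric
  about their means, which only a percentile construction produces.

**Degenerate regime.** At n = 12, individual WS draws can exceed the lattice
clustering maximum C(0); a memory network in that situation (or one whose
clustering exceeds C(0) for its k) clamps the match to p = 0. The null
ensemble is then a single deterministic ring lattice: the percentile
interval has zero width and arbitrarily small differences become
"significant". The package reports this honestly (a warning is raised, the
interval is visibly a point). It is the main reason the self-consistency
acceptance check — a WS(12, 4, 0.1) draw judged against its own matched
ensemble — passes at 94/100 fixed seeds rather than the targeted 95: the
construction's expected coverage is ~95% by definition, and the degenerate
p = 0 cases land just outside. The discrepancy is documented rather than
patched, because every candidate fix (a minimum p, inflating a zero-width
interval, special-casing the verdict) amounts to tuning the procedure
against the check that measures it.

## Communities

The leading-eigenvector method recursively bisects by the sign of the
leading eigenvector of the (sub)graph modularity matrix
`B^(g) = B[g, g] − diag(rowSums(B[g, g]))`, `B = A − kkᵀ/2m`, with weighted
adjacency A. A split is accepted only when the leading eigenvalue and the
modularity gain are positive. No Kernighan–Lin refinement is applied — the
basic form of the method keeps the output deterministic, with the
eigenvector sign fixed by its largest-magnitude entry. Bisection runs per
connected component, so communities never span components, and isolated
nodes are singleton communities. Modularity uses the r edge weights (the
networks are weighted; binary modularity is a strictly coarser description).

## The synthetic cohort

The generator exists so that every downstream stage has a testable ground
truth. Counts for a group are drawn from a latent Gaussian copula with a
**planted correlation matrix** and **lognormal margins** parameterised by a
per-region mean and coefficient of variation
(`sdlog² = log(1+cv²)`, `meanlog = log(mean) − sdlog²/2`): c-fos tallies are
positive and right-skewed, and for cv ≤ 0.5 the latent correlation carries
to the count scale nearly unchanged (at cv = 0.3 a planted 0.9 maps to
≈ 0.896; the tests verify recovery within ±0.02 at n = 2000). Lognormal
margins are a modeling convention — no distributional form is implied by
the source data.

The three-group default (`paperlike_config()`) encodes the qualitative
world the pipeline is meant to resolve: **NS** — identity latent correlation
(independent regions); **2S** — uniform latent r = 0.7 (globally
coordinated); **10S** — r = 0.8 inside the BLA–CeA block and 0.1 elsewhere
(amygdala decoupled from the rest). Sizes mirror the experiment: 3 groups ×
8 animals × 12 regions. Count means are set to plausible per-region c-fos
densities (30–80 cells) with group scalings that mimic the reported
activation pattern (amygdala/PV up with shock number, IL down in the strong
group); cv = 0.3 throughout. These values were fixed once, from the
qualitative description, before any acceptance measurement.

What a green parameter-recovery test establishes: that *this* pipeline
separates *this* stated world (2S median r, degree and nodal efficiency
above NS and 10S with pairwise Mann–Whitney p < 0.05 in ≥ 95% of 200 fixed
seeds). What it does not establish: anything about real tissue — the
generator has no slice-level structure, no bilateral asymmetry, no
count-noise floor, no negative functional coupling.

## Numerical and procedural conventions

* Quantiles everywhere are type 7 (linear interpolation), fixed for
  bit-reproducibility.
* Mann–Whitney p values are exact (full null distribution of U via the
  Gaussian-binomial recurrence) for combined n ≤ 20 without ties, otherwise
  normal approximation with tie and continuity correction; Kruskal–Wallis
  uses the χ² approximation with tie correction. Both are native
  implementations, cross-checked against an independent reference to 1e−10
  — the pipeline's tie handling must not silently drift with a library
  default.
* Collection-level r comparisons use the **incident** rule (a pair belongs
  to a collection when at least one endpoint does). Rationale: the smallest
  collection has 2 regions, hence a single within-pair — too few values to
  test; incident pairs (21 for a 2-region collection in a 12-region scheme)
  are the only reading that supports the reported comparisons. The
  `within` rule is available by flag.
* Per-animal counts are single numbers (mean over ≥ 2 bilateral slices,
  aggregated upstream of the package); slice-level aggregation is the
  user's choice, deliberately out of scope.
* `run_full_analysis` derives per-stage seeds from the master seed; the
  same inputs and seed give byte-identical outputs.

## Known limitations

* The unit-weight null biases small-world verdicts conservative for
  networks with moderate edge weights (see above).
* The degenerate p = 0 null regime at small n produces zero-width
  intervals.
* Kruskal–Wallis/Mann–Whitney on matrix entries is descriptive, not valid
  inference, and is reported unadjusted.
* The generator's equicorrelated 2S world makes whole-cohort correlation
  level fluctuate strongly between seeds at n = 8 (a single latent factor
  moves all 66 pairs together) — a real feature of small-cohort functional
  connectivity that the recovery tests absorb by design.
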