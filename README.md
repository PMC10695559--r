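# fosnet — functional brain networks from regional c-fos counts

`fosnet` is an R package for the network-level analysis of regional
immediate-early-gene activation. The motivating experiment: rats recall a
contextual fear memory of varying strength (no-shock control **NS**, mild
**2S**, strong **10S**; 8 animals per group), c-fos⁺ cells are counted in 12
fear-circuit regions (hippocampal DG/CA3/CA1, amygdalar BLA/CeA, cortical
RSC/IL/PL/Cg1/Cg2, thalamic Re/PV), and the question is how *coordinated*
activity across regions — not activity per region — changes with memory
strength. The package takes per-animal count tables and produces, per group:

1. **Correlation matrices** — across-animal Pearson r for every region pair,
   diagonal zeroed; compared across groups overall and within region
   collections (Amyg, HPC, PFC, Other) by Kruskal–Wallis + Mann–Whitney.
2. **Functional networks** — edges are correlations strictly above a single
   pooled threshold, mean + 1 SD of all groups' r values; edge weight = r.
3. **Graph metrics** — degree; betweenness on unweighted geodesics with
   fractional credit for ties; nodal efficiency
   `E(i) = mean_j 1/d(i,j)` with weighted distances `d` using edge length
   `1/r`; global efficiency = mean nodal efficiency; node rankings.
4. **Small-world null comparison** — 1000 Watts–Strogatz networks matched in
   size, even lattice degree k ≈ mean degree, and clustering coefficient
   (rewiring p found by Monte-Carlo bisection); the difference in global
   efficiency is summarised by its mean and a 95% percentile interval.
   An interval containing 0 ⇒ efficiency consistent with a small-world
   architecture.
5. **Communities** — leading-eigenvector spectral bisection of the weighted
   modularity matrix, no refinement step, deterministic.

A synthetic-cohort generator (latent Gaussian copula, lognormal margins,
planted interregional correlation) stands in for the original data so the
entire pipeline is testable offline.

## Worked example

```r
library(fosnet)
cohort <- generate_cohort(paperlike_config(n = 8, seed = 1))
res <- run_full_analysis(cohort, control = "NS", replicates = 1000, seed = 1)
print(res)
```

```
fosnet analysis
  groups: NS, 2S, 10S
  pooled edge threshold: r > 0.5974
  NS: 2 edges, global efficiency 0.021, null mean diff 0.409 [0.409, 0.409]
  2S: 24 edges, global efficiency 0.472, null mean diff 0.165 [0.165, 0.165]
  10S: 9 edges, global efficiency 0.169, null mean diff 0.261 [0.261, 0.261]
```

The threshold 0.597 is the mean + 1 SD of the 3 × 66 pooled correlations.
The mild-memory (2S) network is densely connected (24 of 66 possible edges
survive) and far more efficient than the control or strong-memory networks,
reproducing the qualitative fingerprint the pipeline is built to detect.
Zero-width intervals arise when the clustering match saturates at the ring
lattice (p = 0), making the null ensemble deterministic — see the vignette
for why this happens at small n and how to read it.

```r
print(res$r_comparisons$all)
```

```
Group comparison (Kruskal-Wallis + pairwise Mann-Whitney)
  omnibus: H = 41.69, df = 2, p = 8.856e-10
  medians: NS = 0.0162, 2S = 0.472, 10S = 0.161
  NS vs 2S: U = 825, p = 7.488e-10
  NS vs 10S: U = 1688, p = 0.02589
  2S vs 10S: U = 3150, p = 9.805e-06
```

Median interregional correlation is highest in the mild-memory group — the
coordinated-activity signature. Community structure of the 2S network
(`print(res$partitions[["2S"]])`) splits it into 3 modules with Q = 0.23.

All artifacts (matrices, edge lists, metric tables, replicate efficiencies,
partitions, a JSON report) are written when `out_dir` is supplied, and the
same seed reproduces them byte-for-byte.

## Command line

```sh
fosnet simulate --preset paperlike --n 8 --seed 3 --out counts.csv
fosnet analyze --counts counts.csv --control NS --reps 1000 --seed 3 --out run/
```

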