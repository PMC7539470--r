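# stigmanet

Analysis of plant–plant **pollen-transfer networks** built from stigmatic
pollen loads. In communities of co-flowering, insect-pollinated plants,
stigmas accumulate conspecific pollen (CP) and heterospecific pollen (HP)
from other species. Counting grains per donor taxon on sampled stigmas
yields, for each community, a directed weighted network: a link
*a → b* with weight *w* means *w* identified grains of species *a* were
found on stigmas of species *b*. `stigmanet` is for community ecologists
who have such per-stigma count tables (plus floral-trait and abundance
surveys) and want the full analysis chain behind published pollen-transfer
studies, reproducibly and with every stage testable.

## What it computes

* **Networks and totals** — unipartite directed networks per community,
  with off-plot donor taxa (pollen sources never sampled as receivers)
  flagged; descriptive totals (stigmas, CP/HP grains, links).
* **Degrees and hub roles** — in-/out-degree, grain-weighted degrees,
  hub-donor / hub-receptor / neutral classification (strict inequality of
  in- vs out-degree), and the degree standardization
  `y' = (deg/S · (n−1) + 0.5)/n` that maps degrees into (0, 1) for beta
  regression.
* **Modules** — weighted modularity

  `Q = 1/(2m) Σ_ij [W_ij − γ k_i k_j / (2m)] δ(c_i, c_j)`

  on the symmetrized adjacency `W = A + Aᵀ`, resolution γ = 0.7 by
  default, maximised by a fully seeded Louvain implementation; repeated
  runs (default 25) are grouped up to label permutation and a partition
  is accepted only above 80% run frequency, with exact ties reported as
  *co-optimal*. An exhaustive set-partition oracle validates the
  optimiser on small graphs.
* **Community statistics** — Shannon–Wiener diversity, OLS of modularity
  on community parameters (with an ln(Q+1) normality fallback), and mixed
  models with community and species random intercepts: beta GLMMs for
  standardized degrees, Poisson GLMMs for weighted degrees, and a
  binomial GLMM with likelihood-ratio test and Nakagawa–Schielzeth R²
  for per-stigma HP proportions.
* **Trait importance** — random-forest classification of module
  affiliation from six floral traits measured on individuals
  (ntree = 10000, mtry = 2 by default), with OOB error and permutation
  importance.
* **Synthetic communities** — `generate_community()` plants known module
  structure (trait centroids, abundance-weighted HP donation, off-plot
  donors, a 10% unknown-grain fraction) so every stage can be checked
  against ground truth.

## Worked example

```r
library(stigmanet)

d   <- generate_community(sim_config(n_species = 12, n_modules = 3, seed = 42))
net <- build_transfer_network(d$stigmas,
                              flowering_species = d$flower_survey$species)
net
#> Pollen-transfer network: synthetic
#>   12 taxa (12 on-plot, 0 off-plot donors), 38 links
#>   145 identified heterospecific grains on links, 8 unknown

donor_receptor_percentages(compute_degrees(net))
#> pct_donor pct_receptor    pct_both
#>  33.33333     41.66667    25.00000

cons <- consensus_partitions(net, n_runs = 25, resolution = 0.7, base_seed = 1)
cons
#> Consensus over 25 Louvain runs (gamma = 0.7, threshold > 0.8):
#>   100% of runs: 3 module(s), Q = 0.4204
#>   -> one partition accepted

fit_module_classifier(d$traits, d$true_modules, n_trees = 1000, seed = 1)
#> Module classification (random forest): OOB error 1.67%
#>   60 individuals, 3 modules, ntree = 1000, mtry = 2
#>   most important traits: style_length_mm, nectar_tube_width_mm, inflorescence_diameter_mm
```

The consensus finds the three planted modules in every run (Q = 0.42 at
γ = 0.7) and accepts that partition; the forest separates the modules
almost perfectly from individual trait measurements (1.67% of
individuals misclassified out-of-bag). `run_pipeline()` chains all of
this — plus the mixed models and per-community serialization (GraphML,
CSV, JSON) — over a multi-community study, deterministically from one
base seed; `scripts/run_pipeline.R` is a shell wrapper around it.

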