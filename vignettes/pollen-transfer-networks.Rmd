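---
title: "Pollen-transfer networks from stigmatic pollen loads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen-transfer networks from stigmatic pollen loads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stigmanet)
```

## The problem

When insect-pollinated plants share flower visitors, a stigma accumulates
not only conspecific pollen (CP) but also heterospecific pollen (HP) from
other species. Counting the grains on senescent stigmas, per donor taxon,
turns a community into a *directed, weighted pollen-transfer network*: a
link $a \to b$ means grains of species $a$ were found on stigmas of
species $b$, weighted by the total number of such grains. This package
builds those networks from per-stigma count tables, summarises them
(degrees, hub roles, descriptive totals), detects modules of species that
preferentially share pollen, and relates network structure to floral
traits and community parameters. A synthetic-community generator with
planted module structure makes every stage testable against known ground
truth.

## Data model

Stigma tables are long-format CSV: one row per (stigma, donor taxon),
with the reserved donor keys `CONSPECIFIC` (always present, possibly
zero) and `UNKNOWN` (grains that could not be identified). Unknown grains
never form links but are retained in heterospecific totals, because HP
loads are enumerated before donor identification. Donor taxa absent from
the community's flowering-species list are flagged *off-plot*: they
donate (from the surroundings, or from earlier flowering) but are never
sampled as receivers, so their in-degree is structurally zero. When a
grain's identity is ambiguous between candidates, the strictly more
abundant candidate is assumed (`resolve_ambiguous_donor()`); an abundance
tie raises an error rather than picking arbitrarily, since a silent
arbitrary choice would corrupt the network.

## The synthetic-community generator

`generate_community()` simulates one community under the minimal
generative model that reproduces the statistical structure the analysis
assumes:

* **Modules.** Species are assigned to `n_modules` pollen-sharing
  modules in balanced round-robin order.
* **Traits.** Module centroids for the six floral traits (stamen length,
  inflorescence diameter, nectar-tube depth and width, display size,
  style length; all mm) sit on a regular grid separated by
  `trait_centroid_separation` within-module standard deviations; species
  means are jittered around their centroid and individuals around their
  species mean, both with standard deviation `trait_sd` (default 0.5 mm),
  truncated at zero. Five individuals are measured per species, the usual
  field protocol.
* **Abundance.** Flower abundances are log-normal
  (`meanlog = 4`, `sdlog = 2`), spanning single flowers to thousands per
  transect, as flower surveys of species-rich grasslands do.
* **Loads.** Each stigma carries a negative-binomial conspecific load
  (`mu = 100`, `size = 0.6`, i.e. strongly overdispersed) plus
  independent Poisson heterospecific contributions from every other
  taxon with mean `rate * abundance / mean(abundance)`, where `rate` is
  `hp_rate_within` (default 0.3) for same-module donors and
  `hp_rate_between` (default 0.03) otherwise, including off-plot donors.
  Each HP grain is then relabelled `UNKNOWN` independently with
  probability 0.10, so identified plus unknown grains equal the grains
  generated, exactly.

The default rates were calibrated once so that a 16-species community
reproduces the scales observed in field studies of this design: tens of
links per community rather than a saturated graph, a mean conspecific
percentage near 90%, one to a few HP grains per stigma, and
right-skewed in- and out-degree distributions (most species hold one or
two links, a few abundant donors hold many). The heavy-tailed abundance
distribution is what produces the skew: donation probability is
proportional to abundance, so a handful of abundant species dominate
transfer.

What the generator does **not** emulate: spatial structure within plots,
phenology inside a sampling round, pollinator identity or behaviour, and
donor misidentification other than the uniform unknown fraction. Tests
that pass on synthetic data therefore validate the *pipeline* — not any
claim about a particular field system.

Randomness is organised as one stream per dataset plus deterministically
derived per-species substreams, so an identical `sim_config()` yields a
bit-identical dataset and adding a species does not reshuffle the others.

## Modularity and consensus

Module detection maximises weighted modularity with a resolution
parameter $\gamma$:

$$Q = \frac{1}{2m}\sum_{ij}\left[W_{ij} -
  \gamma\,\frac{k_i k_j}{2m}\right]\delta(c_i, c_j),$$

computed on the symmetrized adjacency $W = A + A^{\mathsf T}$ (with
$k_i$ the weighted degree and $2m = \sum_{ij} W_{ij}$). Symmetrization
mirrors how general-purpose network software treats directed graphs when
asked for classic Newman modularity; the Leicht–Newman directed variant
is available through `modularity_score(..., mode = "directed")` for
sensitivity analysis. The default resolution is $\gamma = 0.7$, which
favours slightly coarser modules than $\gamma = 1$ — appropriate for
sparse networks of tens of species where singleton modules are not
ecologically meaningful.

The optimiser is the greedy two-phase Louvain scheme: local moving of
nodes between modules until no gain, then aggregation of modules into
supernodes, repeated until a full level yields no improvement. Two
numerical choices make runs reproducible: randomness enters *only*
through the seeded node visit order, and ties in the local-moving step
break toward the lowest candidate module index. Because Louvain is a
heuristic, the package also ships an exact oracle
(`brute_force_partition()`) that enumerates all set partitions for
graphs of up to ten nodes; the test suite verifies that Louvain never
exceeds the exact optimum and attains it on at least 90% of a random
battery.

Stochasticity across runs is handled by consensus:
`consensus_partitions()` repeats the optimiser (default 25 runs, seeds
`base_seed + 1..n_runs`), groups partitions up to label permutation, and
accepts a partition only when it appears in more than 80% of runs. When
no partition clears the threshold and at least two tie for the top
frequency, the result is flagged *co-optimal* and all tied partitions
are reported with their modularities — a situation that occurs in real
communities and must be surfaced, not hidden by an arbitrary choice.

Edgeless networks have undefined modularity and raise an error; callers
(including the pipeline) treat such communities as having no module
structure.

## Degrees, hubs and standardization

In-degree counts the species from which a plant received HP, out-degree
the species to which it donated; weighted versions sum grains. A species
with out-degree strictly above in-degree is a *hub-donor*, the converse
a *hub-receptor*, equality (including isolates) *neutral*. Hub
percentages use, by default, only species holding at least one link —
the convention consistent with published community tables — with all
sampled species selectable.

For beta regression, degrees are standardized by the number of flowering
plant species $S$ and compressed off the boundaries:

$$y' = \frac{(y \cdot (n-1) + 0.5)}{n}, \qquad y = \text{degree}/S,$$

with $n$ the number of observations entering the regression. The result
lies strictly in $(0,1)$ for every admissible input, as the beta family
requires. $n$ is a modelling choice, not a property of the network, so
`compute_degrees(standardize = TRUE)` defaults it to the number of
on-plot species in the table and `standardize_degree()` exposes it
directly for pooled fits.

## Community statistics

Diversity is the Shannon–Wiener index $H' = -\sum p_i \ln p_i$ (via
vegan). Community-level modularity is regressed on one parameter at a
time by OLS. The response is ln(Q+1)-transformed when a Shapiro–Wilk
test on the raw-model residuals signals non-normality at a screening
level of $\alpha = 0.10$; the lenient level is deliberate, because
normality tests have very little power at the typical handful of
communities (n ≈ 9), and the transform is harmless when the response is
already near-normal. `transform = "none"` or `"ln1p"` override the
trigger.

Species-level analyses are mixed models with random intercepts for
community and species, one fixed predictor per model (traits are
assessed one at a time, matching the reporting convention of per-trait
z statistics):

* standardized degrees — beta family, logit link, constant precision
  (glmmTMB, Laplace approximation), Wald z;
* weighted degrees — Poisson, log link (lme4);
* per-stigma HP proportion — binomial on `cbind(hp, cp)`, tested by a
  likelihood-ratio test against the random-effects-only model
  ($\chi^2_1$), with Nakagawa–Schielzeth $R^2_{marginal}$ and
  $R^2_{conditional}$ computed on the link scale using the logit
  observation-level variance $\pi^2/3$.

Non-convergent fits follow a staged policy: refit restarting from the
previous estimates with a larger iteration budget, then switch optimizer
(bobyqa for lme4, BFGS for glmmTMB). The path taken is recorded in the
result; exhausting the policy is an error, never a silent fallback.
All-conspecific data put the fitted HP proportion at the boundary; the
model is not fitted and the result is flagged instead.

These wrappers are validated by simulation, not against any particular
dataset: with planted slopes, all three families recover the truth
within a few percent on average, Wald intervals cover at close to
nominal rate, and under the null the type-I error stays near 5% and the
LRT statistic behaves like $\chi^2_1$. The suite uses 200 replicates of
a 9-community × 20-species design — large enough for stable Monte-Carlo
estimates of those rates while keeping the whole suite quick.

## Trait importance

Whether floral traits predict module affiliation is assessed with a
random forest classifying trait *individuals* (not species means) into
modules, so within-species variation enters the out-of-bag error. The
defaults are 10,000 trees with `mtry = 2`; the property tests use 1,000
trees, which is ample for stable rankings at a few dozen individuals.
Importance is unscaled permutation mean-decrease-in-accuracy, with mean
decrease in Gini as an alternative; a pure-noise trait scores near zero
under permutation importance, which makes it the better default for
reporting. Communities in which consensus finds a single module cannot
be classified and raise a typed error the pipeline converts into an
omitted report, mirroring how single-module communities are dropped from
published trait-importance tables.

## The pipeline

`run_pipeline()` chains the stages per community (network → totals →
degrees → consensus → serialization) and across communities
(community-parameter table → modularity LMs → GLMMs → random forests),
writing GraphML and edge-list networks, CSV tables and JSON summaries
under one output directory. Every stochastic stage is seeded from
`base_seed`, so reruns are byte-identical. Stage failures halt with the
stage name and offending community. Off-plot donors are included in
module detection by default (their links are part of the network);
`include_offplot = FALSE` restricts detection to sampled species, which
changes only module-derived outputs.

## Known limitations

* Louvain with a resolution parameter is the only optimiser; no Leiden
  or Infomap alternatives, and no significance test of modularity
  against null networks.
* The directed-modularity convention differs between tools; the package
  reports the symmetrized value by default and never relies on matching
  any particular tool's printed Q.
* Beta-GLMM $R^2$ values are not reported (the observation-level
  variance of the beta family on the logit scale has no agreed
  delta-free form); $R^2$ is reported for the binomial model, where the
  decomposition is standard.
* The generator's ground truth makes recovery tests possible but also
  idealised: real communities violate the planted-partition assumption
  in ways (gradients, nestedness, phenology) the tests do not probe.
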