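---
title: "Compositional phi-proportionality networks for rotation-cropped soil communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional phi-proportionality networks for rotation-cropped soil communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

phiconet implements the downstream statistics for a two-field, two-crop,
three-stage soil amplicon survey: 36 samples (2 fields x 2 crops x 3 growth
stages x 3 replicates), with sequence variants (SVs) of a eukaryotic (18S)
or prokaryotic (16S) marker as the taxonomic unit. Everything upstream of
the SV count table — read joining, denoising, chimera removal, taxonomic
assignment — is out of scope; the package consumes plain TSV tables.

The analytical core is compositional. Read counts carry only relative
information, so association between SVs is measured by proportionality
rather than correlation: for clr-transformed abundances,

$$\phi_{i \to j} = \frac{\mathrm{Var}_s\!\left(\mathrm{clr}_i(s) - \mathrm{clr}_j(s)\right)}{\mathrm{Var}_s\!\left(\mathrm{clr}_i(s)\right)},
\qquad \mathrm{clr}_i(s) = \log p_i(s) - \tfrac{1}{D}\sum_j \log p_j(s),$$

with variances taken over the samples $s$ of one field x crop group. Two
SVs whose abundances track each other multiplicatively have a near-constant
log-ratio and hence $\phi \approx 0$; independent SVs of equal clr variance
give directional $\phi \approx 2$. $\phi$ is invariant to the log base and,
in exact arithmetic, to per-sample count scaling. An undirected network is
built per group by connecting pairs with $\phi$ strictly below a threshold
(0.12 for 18S, 0.08 for 16S), and its nodes (nSVs) are classified across
the four group networks into core (top 10% / 5% by degree, ceiling-k with
boundary ties included), common (present in all four), and crop- or
field-specific (present in both networks of one crop/field, absent from
both of the other).

## Counting uncertainty: the Dirichlet Monte-Carlo clr

A zero or small count says little about the underlying proportion. Instead
of a single clr transform, `clr_ensemble()` draws, for each sample, $M$
proportion vectors from $\mathrm{Dirichlet}(\text{counts} + \lambda)$ and
clr-transforms each draw; $\phi$ is computed per instance (directional,
then symmetrized) and aggregated across instances. Low-count SVs thereby
acquire instance-to-instance log-ratio variance, which inflates their
$\phi$ and keeps statistically unsupported pairs out of the network. This
is deliberately conservative: it protects edge precision at the cost of
recall on rare SVs (see *Limitations*).

Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| prior $\lambda$ | 0.5 | Jeffreys-style pseudo-count, the convention of Dirichlet Monte-Carlo log-ratio tooling |
| instances $M$ | 128 | the same tooling's convention; ensemble mean stable to ~1% |
| symmetrization | max of the two directions | an edge then requires *both* directions under threshold (conservative); `min`/`mean` available |
| instance aggregation | mean | `max` available |
| variance | unbiased ($n-1$) | small group sizes ($n = 9$) |
| log base | natural | immaterial: $\phi$ is a variance ratio |

The directionality and aggregation conventions of the wrapped function the
motivating analysis used are not documented; the choices above are declared
defaults, not inferred intent, and each has a config switch.

Group-wise practicalities: SVs with zero total count in a group are removed
before the group's clr (the log-ratio of an all-zero feature is
meaningless) but retained in the table; features with zero sample variance
get undefined $\phi$ rows and are excluded from network building; a
`min_prevalence` config (default 1 nonzero sample) is exposed because
whether the original analysis prevalence-filtered beyond group subsetting
is not stated.

## Diversity, ordination, chemistry

* **Rarefaction** subsamples each sample without replacement to a common
  depth (default: the minimum sample total), one draw, seed recorded.
  Rarefied counts feed *only* the alpha/beta-diversity stage; clr/phi and
  RDA use the unrarefied table.
* **Shannon index** in nats ($-\sum p \ln p$); pairwise group differences
  by the Tukey–Kramer studentized-range test with pooled within-group
  variance and the harmonic form for unequal $n$.
* **Bray–Curtis / NMDS**: ordination minimizes Kruskal stress-1 by SMACOF
  majorization (Guttman transform) alternated with pool-adjacent-violators
  monotone regression on dissimilarity ranks (primary tie approach: ties
  impose no order constraint). Twenty starts by default; the first start is
  seeded from classical scaling, the rest are random; a start stops when
  stress improves by less than 1e-7 (or stalls), so the per-iteration
  stress trace is non-increasing by construction.
* **PERMANOVA** (one-way): $SS_\text{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2$,
  within-group analogues per group, pseudo-$F$ with $(k-1, n-k)$ df. The
  p-value uses the $+1$-corrected permutation estimate (999 permutations by
  default, matching a p floor of 0.001), except that designs with at most
  5000 distinct labelings are enumerated exactly.
* **Chemistry**: twelve parameters on the 12 composite (field, crop, stage)
  cells. Heatmap preprocessing divides each cell's value by the parameter's
  column total (columns sum to 100%); clustering is complete linkage
  (farthest neighbor) on Euclidean distances of that percentage matrix —
  the linkage is prescribed, the distance is our choice.
* **RDA**: the point-estimate clr matrix (single Dirichlet-free instance;
  the source analysis passes "the log-ratios" without ensemble detail) is
  centred and regressed on standardized chemistry; SVD of the fitted values
  gives constrained axes with eigenvalues $d_a^2/(n-1)$. Chemistry rows are
  broadcast from the 12 cells to the 36 samples — the only alignment
  consistent with ordinating 36 communities against 12 composite
  measurements. Standardization is the default (units are incommensurable)
  with a flag for raw units, which the source does not specify. Biplot
  vectors are parameter-site-score correlations scaled by each axis' share
  of constrained variance. The per-parameter association table uses plain
  clr–parameter Pearson correlation over the top-350 most abundant
  features; the rule behind the original supplementary table is not given,
  so this simple score is declared.

## The synthetic world

`generate_community()` states a world, not a fit to data:

* log basis abundance of SV $i$ in sample $s$:
  $b_i + L_{s,m(i)} + \varepsilon_{s,i} + g_{i,\text{group}(s)}$, observed
  counts multinomial at a uniform depth in [20 000, 60 000] (typical
  desk-scale amplicon libraries; overdispersion beyond multinomial is not
  modelled).
* $b_i \sim N(0, 1)$: log-normal rank-abundance heterogeneity. Real SV
  tables are *more* skewed; 1.0 keeps most SVs observable at these depths
  while still exercising rare-feature behaviour.
* planted modules: members of module $m$ share the per-sample latent
  $L_{s,m} \sim N(0, 1)$ plus small idiosyncratic noise (sd 0.05);
  non-module SVs instead receive *independent* per-sample variation with
  the same sd as the latent. Without that background variability every
  background pair would have a near-constant log-ratio and pass the phi
  threshold — the planted structure would be undetectable by design.
* group effects: per (SV, group) log-fold shifts $N(0, 1.25)$. The sd was
  set so the rarefied Bray–Curtis PERMANOVA on simulated data lands at
  $R^2 \approx 0.5$–$0.63$, the separation regime the motivating field
  study reports ($R^2$ 0.51–0.66). An earlier value (0.5) was corrected
  because it measurably failed this stated purpose ($R^2 \approx$ 0.2).
* chemistry: per-cell value = baseline + matching shifts + Gaussian noise
  (sd = 5% of the parameter's baseline, since parameters span four orders
  of magnitude), clipped at 0, water content clipped to [0, 1]. The default
  effect map encodes the qualitative field pattern: nitrogen and
  conductivity high under early/middle maize (pre-sowing fertilizer), humus
  high in field 1 (green manure the year before), water and exchangeable
  nutrients high in field 2.

What a green recovery test establishes: that the clr/phi/threshold/
classification machinery finds planted multiplicative co-variation and
nothing else, in a community with realistic depth, rank-abundance and
group structure. What it does not establish: performance on real data with
stronger sparsity, overdispersion, taxonomic misassignment, or non-modular
covariance.

## Numerical choices and degenerate inputs

* Counts are validated as non-negative integers and stored as doubles
  (exact to $2^{53}$; avoids 32-bit overflow on totals).
* `filter_by_length()` removes strictly shorter SVs (`<` as printed for the
  407/400 bp cutoffs); missing lengths make it a warning no-op.
* Taxonomy keeps the literal string `"NA"` as an ordinary category.
* Tukey–Kramer with zero pooled variance and unequal means reports the
  machine floor and a `degenerate` flag rather than p = 0.
* PERMANOVA permutation comparisons use `F_perm >= F_obs - 1e-12` to avoid
  losing exact ties to floating-point noise.
* phi clamps tiny negative `Var(clr_i - clr_j)` (floating-point residue of
  perfectly proportional pairs) to 0.
* Cluster numbering: components sorted by size descending, ties by
  lexicographically smallest member, so "cluster 1" is reproducible.
* Core-set selection: `k = ceiling(fraction * n)` and all boundary-degree
  ties included — no node with an equal claim is dropped arbitrarily.
* NMDS on degenerate inputs (all-equal dissimilarities) returns the best
  stalled configuration with `converged = FALSE` rather than erroring.
* The spec-level definition of the point-estimate clr,
  $(\text{counts}+\lambda)/\text{sum}$, is only asymptotically scale
  invariant for $\lambda > 0$; exact invariance holds at $\lambda = 0$.

## Limitations

* Recall of planted proportional pairs degrades for SVs whose per-sample
  counts fall to single digits: multinomial + Dirichlet sampling noise
  contributes roughly $1/\text{count}$ per sample to the log-ratio
  variance, pushing $\phi$ over the threshold. At the default world
  (baseline sd 1.0, group sd 1.25, depths 20–60k, 9 samples per group)
  per-group edge precision is 1.0 but recall plateaus around 0.6–0.85;
  recall $\ge 0.9$ requires a near-uniform community (baseline sd
  $\lesssim 0.5$) without group structure. This is a property of
  finite-depth phi estimation, not of the implementation (which matches a
  brute-force oracle to 1e-10).
* One-way PERMANOVA only; no nested/stratified designs.
* Bray–Curtis is a semimetric; NMDS handles that by construction, but no
  phylogeny-aware distances are provided.
* The chemistry generator produces cell-level composites only (as
  measured); replicate-level chemical variation is not modelled.
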