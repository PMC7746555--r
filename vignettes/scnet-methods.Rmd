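---
title: "Structural covariance network analysis with scnet: models, choices, limits"
author: "scnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

Structural covariance networks describe the coordination of regional brain
morphology across a group of subjects: two cortical regions are "connected"
when their cortical thickness covaries across individuals. `scnet`
implements the complete group-comparison pipeline for such networks, from a
subjects-by-regions thickness table to permutation-tested differences in
graph-theoretic parameters.

The pipeline is, per group:

1. **Correction.** For each of the 68 Desikan-Killiany regions, an ordinary
   least-squares regression removes the effects of age, sex and the
   subject's global mean cortical thickness (the unweighted mean of the 68
   regional values). The residuals — "corrected cortical thickness" — are
   what covary in the network.
2. **Correlation.** Pearson correlations across subjects between every pair
   of regions give a symmetric 68 × 68 matrix R; the diagonal is set to 0.
3. **Binarization at fixed density.** For a density D, the E =
   round(D · N(N−1)/2) strongest *positive* correlations become edges of an
   undirected, unweighted graph; negative correlations never become edges.
   Fixing density rather than a correlation threshold makes groups
   comparable: both groups' networks have exactly the same number of edges.
4. **Graph parameters.** Clustering coefficient Cp, characteristic path
   length Lp, global and local efficiency, transitivity, Newman modularity
   Q, and nodal degree/clustering/betweenness (each also divided by its
   network mean). Cp and Lp are additionally normalized by the mean of
   degree-matched rewired random networks, giving gamma, lambda and the
   small-world index sigma = gamma/lambda.
5. **Density range.** Analyses run over a grid of densities. The lower
   limit is the smallest probed density at which both groups' networks are
   connected; the upper limit is the largest at which both have
   sigma > 1.2. Per-metric curves are summarized by the trapezoidal area
   under the curve (AUC) across the grid.
6. **Inference.** Group labels are randomly reassigned (preserving group
   sizes); the whole per-group pipeline is rerun per repetition; two-sided
   p-values use the add-one rule (b + 1)/(m + 1). 95% null bands per
   density are the 2.5/97.5 percentiles of the permutation distribution.

A worked example is in the README; `runPipeline()` drives all stages from a
YAML or list configuration and writes tidy CSVs plus a JSON manifest.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| density grid | 0.15–0.40, step 0.01 | fraction of possible edges; the step is configurable because published analyses rarely state it |
| sigma rule | 1.2 | small-world cutoff for the upper density limit |
| ensemble size | 100 | rewired random networks behind gamma/lambda/sigma |
| rewires per edge | 10 | attempted degree-preserving swaps per edge |
| permutations | 1000 | label reassignments for inference |
| hub rule | mean + 1.5 SD | inclusive cutoff on nodal betweenness, population SD |
| residualization scope | per-group | regressions refitted inside each (pseudo-)group |

Ensemble size and the rewiring budget are exposed because the literature on
this design typically does not report them; 100 networks and 10 swaps per
edge are conventional toolbox values, and the seeded generator makes any
choice reproducible.

## Design choices where the design was open

**Residualization scope.** Published descriptions say only that regression
removes age, sex and global mean thickness; whether it is fitted per group
or pooled is ambiguous. `scnet` defaults to per-group, matching the
group-wise network construction, and refits inside each permuted
pseudo-group so the null respects the full estimation pipeline. `scope =
"pooled"` is available; permuting then reuses the single pooled fit's
residuals implicitly through relabeling.

**Degenerate global-mean covariate.** The global mean is derived from the
outcomes. When it carries no information beyond the other covariates —
thickness exactly linear in age/sex, or input that is already residualized
— it is dropped from the design rather than fitted against numerical
noise; this also makes residualization idempotent. Degenerate *age* or
*sex* (e.g. a single-sex sample) is a data error and raises an error
naming the column.

**Ties at the density cut.** Equal correlations at the cut rank are broken
by larger r, then lexicographic region-pair order, so thresholding is
deterministic and edge sets are nested across densities.

**Disconnected pairs.** Lp averages over connected pairs only, and global
efficiency counts disconnected pairs as zero efficiency. Observed networks
inside the selected range are connected by construction, but permuted and
rewired networks may fragment, and these conventions keep every repetition
finite. Nodes of degree < 2 score 0 for nodal clustering and local
efficiency.

**Hub rule.** Inclusive (≥) threshold with the population SD; when every
node has equal betweenness (SD = 0) no node stands out and the hub set is
empty rather than universal. Hub comparison defaults to the lower end of
the density range — the sparsest connected network, where betweenness is
most discriminating — with a majority-vote mode across the grid as an
alternative, since published hub analyses rarely state their density.

**Modularity optimizer.** Newman modularity is maximized with the seeded
Louvain heuristic. The standalone `modularityQ()` takes the best of 5
restarts; inside the curve/permutation engine a single seeded restart per
graph is used so that desk-scale permutation runs stay tractable, and the
same procedure is applied to observed and permuted data, which is what the
validity of the permutation p-value requires.

**Permutation seeding.** One global seed derives per-repetition sub-seeds,
so repetitions are order-independent and a run is exactly reproducible;
p-values use the add-one rule and can never be 0.

**Multiplicity.** Regional (nodal) AUC p-values are reported uncorrected —
as is conventional for this design — alongside a Benjamini–Hochberg
adjusted column, so the reader can see both.

## The synthetic cohort generator

No subject-level data ships with the package; `syntheticSpec()` +
`generateCohort()` produce cohorts with *known* ground truth instead. The
generator emulates the structure the pipeline assumes: two groups (default
sizes 67 and 88), 68 regions, baseline thickness 2.5 mm, linear age
(−0.005 mm/year over ages 40–70) and sex (0.02 mm) effects, and residuals
drawn from a multivariate normal whose correlation matrix is a planted
partition: four equal blocks with within-block correlation 0.5 and
between-block correlation 0.2 by default, optionally different per group.
A residual SD of 0.12 mm is typical of regional mean thickness. An
optional "bridge" region correlating only with chosen blocks plants a
high-betweenness connector node. Implied correlation matrices are checked
for positive semi-definiteness before sampling and repaired by eigenvalue
clipping with a warning.

The block family was chosen because it is the simplest correlation
structure with tunable segregation — exactly what modularity and
clustering comparisons need as ground truth — and is
positive-semi-definite by construction for 0 ≤ between ≤ within < 1.

What the generator does **not** emulate: spatial autocorrelation on the
cortical sheet, hemispheric symmetry, non-Gaussian thickness
distributions, site or scanner effects, and any dependence of covariance
on age. Tests that pass on these cohorts therefore validate the
*computational* pipeline — not the biological claim of any particular
study.

One consequence of the model worth knowing: regressing out the global mean
re-centres the correlation distribution, pushing between-block
correlations negative. This is a well-known property of global-signal
removal, not an artifact of the generator; it is why strongly modular
covariance with near-zero between-block correlation can never form a
connected positive-correlation network, and why the number of positive
correlations — hence the maximum achievable density — is limited.

## Validation experiments shipped with the package

The test suite validates the pipeline property-by-property at sizes chosen
for a desk-scale run:

- **Oracle equivalence**: every graph metric equals hand-written
  brute-force implementations (Floyd–Warshall distances, exhaustive
  neighbor-pair counting, all-shortest-path DP, exhaustive partition
  search for Q) on all 208 non-isomorphic graphs with ≤ 6 nodes and 100
  random graphs with ≤ 10 nodes.
- **Small-world null**: Erdős–Rényi graphs (n = 100, mean degree 10) are
  their own degree-matched null, so gamma ≈ lambda ≈ 1 (within 0.15 over
  20 replicates at 50 rewired networks); a ring lattice (n = 20, k = 4)
  gives gamma > 1.
- **Calibration**: on 200 null cohorts (both groups from one spec, 30/30,
  within-block r 0.4, between 0.15) with 200 permutations each over
  densities 0.15–0.35 (step 0.05), the type-I error at α = 0.05 for the
  Cp, Lp and Q AUC differences must lie in [0.03, 0.07]. The density grid
  stops at 0.35 because the positive-correlation budget of this null spec
  makes 0.40 unattainable for occasional samples (see above).
- **Effect recovery**: planting stronger within-block correlation in group
  1 (0.6 vs 0.4, between 0.2, 60/60, densities 0.15–0.25) must yield
  positive Cp and Q AUC differences with p < 0.05 in ≥ 80% of 20
  replicates at 200 permutations.
- **Hub recovery**: a bridge region correlating 0.45 with two of four
  otherwise independent blocks in group 1 only must be detected as a
  betweenness hub at density 0.15 in the affected group only, in ≥ 80% of
  20 replicates. The bridge targets a block subset because a region
  correlated with *everything* is statistically indistinguishable from the
  global mean and is removed by the correction step.
- **Reproducibility**: identical configuration and seed give byte-identical
  output tables.

## Known limitations

- Binary, positive-correlation networks only; no weighted or signed
  variants, no correlation-significance thresholding.
- Permutation inference over gamma/lambda/sigma requires a random ensemble
  per repetition per density and is computationally heavy; the
  ensemble-free metrics (Cp, Lp, efficiencies, transitivity, Q) are the
  practical permutation targets at desk scale.
- The Louvain heuristic gives a lower bound on the true maximum modularity;
  with a single engine restart the bound is occasionally loose, though
  identically so under observed and permuted data.
- Group-level networks mean there is one network per group, not per
  subject; all inference is via label permutation, and no subject-level
  network statistics are available by design.
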