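---
title: "Multi-omics correlation networks for time-course fibrosis studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics correlation networks for time-course fibrosis studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibronet)
```

## The analysis model

Experimental pulmonary fibrosis (the bleomycin mouse model) produces a
characteristic multi-omics time course: a single injury, followed by
inflammation, fibroproliferation and partial resolution over roughly four
weeks. `fibronet` implements an integrative workflow for such studies built
around three data layers measured on the same animals:

* **transcriptomics** — gene counts/TPM for five groups (control and four
  post-injury time points), typically five animals each;
* **metabolomics** — relative peak areas from mass-spectrometry profiling,
  with detection-limit missingness;
* **phenotypes** — pulmonary-function parameters (stiffness index,
  elastance, peripheral airway resistance, FEV, FVC, IC).

The workflow has five statistical stages.

**1. Per-time-point differential analysis.** Each post-injury group is
contrasted against control. For genes the default test normalises counts by
median-of-ratios size factors, transforms to `log2(count/sf + 1)` and
applies a Welch t-test per gene; the stage is deliberately pluggable — any
table of (effect sign, BH-adjusted p) can be substituted, because all
downstream stages consume only those two columns. For metabolites the
pipeline first removes metabolites observed in fewer than two samples of
any time point, imputes the remainder with a per-time-point k-nearest-
neighbour rule, and applies an equal-variance t-test with the log2 ratio of
group means as the effect. Consistency sets summarise the time course:
genes up (down) at *every* time point form DEG-0 (DEG-1); metabolites up
(down) at two or more time points — and never significant in the opposite
direction — form DM-0 (DM-1).

**2. Correlation networks.** All pairwise Spearman correlations are
computed within each omics layer across the pooled samples (the n = 25
design, not within time point: correlating over the full time course is
what lets co-trajectory structure form edges). P-values come from the
t approximation and are BH-adjusted over all tested pairs as one family.
The gene co-expression network (GCN) keeps significant positive pairs
(adjusted p ≤ 0.05) and then only the top 25% most positively correlated of
them; the metabolite correlation network (MCN) keeps all significant pairs
of either sign, with a positive-only switch for situations where
anti-correlated metabolite groups would otherwise be merged by community
detection. Phenotype variables enter the same correlation pass as extra
nodes but are exempted from the positivity and top-fraction filters: a
declining FVC is informative precisely through its negative correlation
with fibrosis-driven genes, and a quantile computed over millions of
gene-gene pairs would be meaningless for a handful of phenotype edges.

**3. Subnetworks.** Communities are found with the Leiden algorithm
(modularity objective, unweighted edges, fixed seed) and relabelled
`0..K-1` in decreasing size order, so label 0 is always the largest
subnetwork. Subnetwork importance is summarised by the average local
clustering coefficient of members, computed on the full network's edges
(not the induced subgraph; both conventions are available). Phenotype
centrality is the number of adjacent omics nodes per phenotype, and
`top_correlates()` ranks a phenotype's neighbours by `|rho|`.

**4. Integration and translation.** Over-representation uses the
upper-tail hypergeometric test; the universe for subnetwork enrichment is
the set of partitioned features of that omics layer (subnetworks are
subsets of the network, so testing them against all measured features
would conflate network membership with subsystem membership — the universe
is configurable). Gene and metabolite subnetworks are *bridged* through a
shared metabolic-subsystem vocabulary: a bridge edge is emitted whenever
one subsystem is significantly over-represented on both sides. Externally
derived gene tracks (temporal trajectory groups with shared transcription
factors) are associated with subnetworks by the same test, with BH applied
across the whole track-by-subnetwork matrix. Cross-species translation
maps mouse genes through a one-to-one ortholog filter and reports overlap
percentages, same-trend fractions (denominator: genes significant in both
species; the mouse-denominator alternative is available) and the
multi-cohort validated set (same sign, significant in mouse and in both
human cohorts).

**5. Perturbation reversal.** Given a disease contrast (disease vs
control) and a perturbation contrast (perturbed-disease vs disease,
e.g. a receptor knockout under injury), a gene is *reversed* when
significant in both with opposite signs. Each subnetwork is scored by its
reversed fraction among disease-dysregulated members and a hypergeometric
enrichment of perturbation-affected genes, BH-adjusted across subnetworks;
the call direction is the median perturbation fold change. Requiring
significance in both contrasts (not merely opposite point estimates) is
the default; the point-estimate mode is exposed as an argument.

## The synthetic-data generator

Every stage is validated against data with known ground truth.
`sim_config()` plants co-expressed modules: a module is a block of
features whose natural-log means follow a shared group-level trajectory
scaled by positive per-feature loadings (uniform in `loading_sd × [0.5,
1.5]`; strictly positive so modules are internally positively correlated,
as co-expression modules are). Counts are negative binomial with variance
`mu + alpha*mu^2`; metabolites are lognormal with the *same* trajectories
(this shared latent structure is what makes gene-metabolite subsystem
bridges discoverable); phenotypes are `sign × trajectory + noise`.
Missingness is abundance-dependent: entries below a global abundance
quantile are censored with fixed probability, mimicking detection limits.

The five default trajectories mirror the canonical patterns seen in
bleomycin time courses: sustained down-regulation with a nadir at day 14;
early up-regulation peaking at days 7–14 with recovery; progressive
up-regulation plateauing after day 14; late up-regulation; and a transient
early spike. The default phenotype panel couples stiffness index,
elastance and airway resistance to the progressive module (stiffness
noiselessly, as a positive control for centrality and ranking checks) and
FEV/FVC/IC to the down-regulated module. Default sizes are 2000 genes and
300 metabolites (half/60% of them planted), five groups of five
replicates, dispersion 0.1, and seed-determined everything: identical
configurations give bit-identical data.

What the generator does **not** emulate: batch effects, library-preparation
artefacts, read-level noise, correlated measurement error between layers,
and realistic pathway topology (modules are disjoint blocks). Passing the
planted-recovery tests therefore demonstrates that the statistical
machinery is implemented correctly, not that real data of this size would
yield equally clean subnetworks.

## Numerical conventions and edge cases

* **Zero-variance features**: excluded from correlation with a warning
  (rank correlation is undefined); z-scored trajectories report zero
  vectors; two-sample tests use the convention p = 1 for equal means and
  p = 0 for unequal means at zero pooled variance, avoiding NaN
  propagation.
* **Top-25% rule**: implemented as keep-first-`ceiling(0.25 m)` after
  sorting by decreasing rho with lexicographic pair-ID tie-break, so the
  edge set is a deterministic function of the input.
* **Label ordering**: community labels are sorted by size with ties broken
  by the lexicographically smallest member, making partitions reproducible
  across runs and node permutations.
* **KNN imputation**: the distance metric and k are not canonical; the
  package uses plain Euclidean distance over co-observed metabolites
  within the time-point group, k = 3 capped at the available observed
  neighbours, and falls back to the within-group mean when no co-observed
  metabolite exists. Imputed values therefore always lie within the
  observed within-group range.
* **Direction-conflict rule**: a metabolite significant up at two time
  points and down at another is excluded from both DM sets rather than
  assigned arbitrarily.
* **BH families**: one family per correlation run (all tested pairs), per
  differential contrast, per subnetwork's subsystem library, across the
  full track-by-subnetwork matrix, and across subnetworks in the reversal
  report. Each choice is recorded in the corresponding output.

## Problem sizes used in validation

The test-suite fixture is deliberately miniature (30 genes, 12
metabolites, 2 phenotypes, 5 groups × 3 samples, seed 1, committed under
`inst/extdata/fixture/`) so that end-to-end regression runs take seconds;
recovery and calibration checks run at the default 2000 × 300 × 25 size,
where the full correlation pass (about 2 million gene pairs) completes in
a few seconds. Null-calibration checks use 2000 features so the binomial
tolerance `0.05 + 2·SE` is meaningful.

## A worked example

```{r example, eval = FALSE}
library(fibronet)

cfg <- sim_config(seed = 0)
sim <- simulate_counts(cfg)
ph  <- simulate_phenotypes(cfg, sim$truth)

sf  <- size_factors(sim$counts)
y   <- log2(sweep(unclass(sim$counts), 2, sf, "/") + 1)
net <- build_gcn(spearman_all_pairs(attach_phenotypes(y, ph,
                                                      base_kind = "gene")))
part <- leiden_partition(net, seed = 0)
part
top_correlates(net, "stiffness_index", k = 5)
```

## Known limitations

The default differential test is a transparent stand-in, not a
shrinkage-based count model; with very small replicate numbers it is less
powerful than dedicated RNA-seq machinery, which can be plugged in by
supplying external differential tables. Community detection on networks
containing negative edges treats them as affinities (the modularity
objective is sign-blind here); use the positive-only MCN switch when
anti-correlated groups must stay separate. Percentages are reported to
two decimals after rounding, so recomputed shares can differ from a
published figure in the last digit.
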