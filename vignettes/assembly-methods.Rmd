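---
title: "Methods: null models, networks and path models for community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null models, networks and path models for community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `assemblyscope`, the
assumptions behind them, the tunable parameters and their defaults, the
design of the synthetic-data generator, and the numerical choices that a
user reproducing or extending the analyses should know about.

## 1. The assembly null models

### βMNTD and βNTI

For samples $k$ and $m$ with relative abundances $f$ and patristic
distances $d$ on a rooted, branch-length-bearing phylogeny,

$$\beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\sum_{i\in k} f_{ik}\,
\min_{j\in m} d(i,j) + \sum_{j\in m} f_{jm}\,\min_{i\in k} d(j,i)\Big].$$

A taxon present in both samples contributes distance zero (conspecifics
count). The unweighted variant replaces $f$ with $1/S$ over present taxa.
βNTI is the standardized effect size of βMNTD against a null that
shuffles tip labels — equivalently, applies one random permutation to the
rows and columns of the patristic matrix — and recomputes βMNTD, by
default `n_null = 999` times. |βNTI| > 2 marks a pair whose phylogenetic
turnover deviates from the null at roughly the 95% level: negative values
mean co-occurring taxa are closer relatives than chance (selection under
similar conditions), positive values mean more distant (selection under
divergent conditions).

**The null pool is the whole supplied tree.** Tips never observed in the
table keep zero weight but remain in the patristic matrix, so the null
asks "could this community be a random draw from the regional pool the
tree represents?". Passing a tree pruned to the observed taxa restricts
the null to the observed pool, which is the conventional choice when no
regional reference tree exists. The two are deliberately distinguishable
because they answer different questions: clustering relative to a
regional pool is invisible to an observed-taxa-only null whenever all
samples occupy the same niche.

Pairs whose null distribution is degenerate (standard deviation below
1e−10, e.g. on an equal-branch star tree, or two samples with identical
supports — both of which make βMNTD invariant under tip permutation) are
masked as `NA` with a warning and excluded from process fractions, never
divided through.

The permutation loop runs in compiled code (`src/bmntd.cpp`); a 24-sample,
200-tip, 999-randomization run takes a few seconds on one CPU.

### RC-bray

The abundance-based Raup–Crick null preserves each sample's observed
richness $S$ and total abundance $N$; draws $S$ taxa sequentially without
replacement with probability proportional to metacommunity *occupancy*
(the number of samples in which a taxon occurs); gives each selected
taxon one individual; and distributes the remaining $N-S$ individuals
multinomially with probability proportional to metacommunity *relative
abundance*. With `n_null` independent null pairs,

$$RC = 2\big[P(BC_\mathrm{null} < BC_\mathrm{obs}) + \tfrac12
P(BC_\mathrm{null} = BC_\mathrm{obs})\big] - 1 \in [-1, 1].$$

Ties get half weight so the statistic stays centred; equality is judged
at 1e−10 to avoid floating-point artefacts. Null communities are drawn
once per sample and paired across draws — each pair's null distribution
is unchanged, at a fraction of the cost. Counts are rounded to integers;
a single-taxon metacommunity is an error (the null is undefined).

### Process classification

With thresholds $T = 2$ (βNTI) and $R = 0.95$ (RC-bray), both exposed in
`null_config()`: βNTI > +T → heterogeneous selection; βNTI < −T →
homogeneous selection; otherwise RC > +R → dispersal limitation; RC < −R
→ homogenizing dispersal; otherwise undominated. These thresholds are the
field-standard defaults for this framework; they are configurable because
they are conventions, not estimates. Per-habitat fractions are computed
over within-layer pairs (the default unit for "which process dominates
this habitat"); cross-layer pairs are available through `pair_values()`.

## 2. Interdomain networks

Edge candidates are Spearman correlations between OTU *relative*
abundances, after a prevalence filter (present in ≥ 1/3 of samples, to
curb tie-heavy spurious edges from rare taxa). Two-sided p-values use the
t approximation on $n-2$ degrees of freedom. Edges require |r| > 0.6 and
p < 0.05 — at $n = 24$ samples the |r| threshold is the binding one
(its null exceedance probability is ≈ 0.002, measured by permutation).
No multiple-testing correction is applied by default because the method
is defined on raw p-values; the candidate table retains all pairs so a
user can apply `p.adjust` before `build_network()`.

P/N is the count ratio of positive to negative edges; a network with no
negative edges reports `Inf` rather than a fabricated number. Robustness
is the mean share of surviving nodes left in the largest connected
component after uniformly removing ⌈f·n⌉ nodes (f = 0.5, 100 replicates,
seeded). Core species are nodes in the top decile of *both* degree and
unnormalized shortest-path betweenness, ties kept.

In the pipeline's per-layer tables a Haldane-corrected ratio
$(P+\tfrac12)/(N+\tfrac12)$ is used *only* where the P/N value feeds a
regression (the path model), because an infinite covariate is unusable
there; the reported `pn_ratio()` is never corrected.

## 3. Important taxa and the perturbation experiment

Depth is encoded ordinally (W = 0, S1 = 1, S2 = 2, S3 = 3) by default; a
midpoint-centimetre encoding is available. A 1000-tree regression forest
of depth on relative abundances yields %IncMSE permutation importance
(out-of-bag convention); ranking ties break lexicographically by OTU id
so rankings are order-invariant. `rfcv` halves the feature set per step
and the selected size is the cross-validation minimum (smallest size on
ties) — exposed as `top_n` rather than hard-coded, since the appropriate
cutoff is data-dependent.

The perturbation experiment removes a taxon set, prunes the tree to the
survivors, re-draws the null over the reduced pool, and reports per-pair
ΔβNTI plus before/after process fractions. An empty removal set is a
bit-exact no-op (same seed, same results), which the tests assert.

## 4. PLS path modeling

`fit_plspm()` implements the Lohmöller alternating algorithm: manifests
standardized; outer approximation in mode A (weights ∝ correlation with
the inner proxy); inner approximation by the path scheme by default
(centroid and factor schemes available); convergence when the largest
outer-weight change falls below 1e−7, error after 300 iterations. Path
coefficients are OLS regressions of each endogenous latent score on its
predecessors; GoF = √(mean communality × mean R²). Latent sign
indeterminacy is resolved by forcing each block's dominant loading
positive. Single-indicator blocks reduce exactly to path analysis on
standardized variables, which anchors the implementation's unit tests.
Manifests with |loading| < 0.7 are pruned iteratively (a block that would
empty keeps its best manifest, with a warning); path significance comes
from a seeded nonparametric bootstrap (percentile intervals, two-sided
sign-crossing p).

The observation unit is the within-layer sample pair: environmental
heterogeneity is the Euclidean distance of standardized physicochemical
vectors, the per-layer P/N ratios are broadcast to that layer's pairs,
and βNTI is the response. Pairs sharing a sample are not independent;
the pipeline records this caveat in its output metadata, and with few
layers the P/N covariates (one value per layer) would make separate
latent blocks collinear, in which case the pipeline collapses them into
a single biotic-interaction block.

## 5. The synthetic-data generator

The generator mirrors the study shape: 4 layers × 6 replicate samples,
one bacterial table with a 200-tip unit-depth pure-birth tree, three
eukaryote tables (40 OTUs each) without trees, physicochemical gradients
(pH, NH₄⁺-N, NO₃⁻-N, TC, TOC, IC) increasing with depth plus noise, and
J = 2000 individuals per sample drawn multinomially.

**Selection regimes are guild niches.** A niche is the set of
`niche_size = 60` tips phylogenetically closest to `niche_clusters = 15`
nucleus taxa chosen from the tree's tightest terminal clusters and spread
by max–min distance. Homogeneous selection uses one niche shared by all
samples; heterogeneous selection gives each layer its own niche around
mutually tree-distant nuclei. Within a niche, each sample assembles by a
colonization lottery (each member present with probability
`occupancy = 0.55`) with near-even log-normal abundances
(`abundance_sdlog = 0.3`), plus a small off-niche immigration background
(`background = 0.004`; zero under heterogeneous selection, where
transient immigrants would collapse the nearest-taxon minima that carry
the between-niche contrast).

This design was arrived at empirically. A Gaussian filter on a Brownian
trait — the textbook picture — selects phylogenetically scattered tips,
because one-dimensional (and even multivariate) Brownian paths cross:
trait similarity does not imply kinship at the tip scale, and the
resulting communities sit near βNTI ≈ −1, not beyond the −2 threshold
that defines the regime. Conversely, turnover generated by heavy
log-normal abundance jitter concentrates weight on few taxa and starves
the statistic. The three ingredients that matter are (i) niche =
terminal clades, so within-niche nearest-taxon distances are small by
construction, (ii) presence/absence turnover with near-even abundances,
which maximizes the effective number of unshared taxa driving the
z-score, and (iii) a pool niche smaller than the tree, so the
tip-shuffle null has contrast to detect. Brownian trait simulation
(`simulate_traits()`) is retained and tested — tip variance = rate ×
depth, kin correlate — and is reported alongside the data; selection
acts on niche membership directly.

**Neutral regimes.** Homogenizing dispersal: one heavily drifted pool
per layer (Dirichlet concentration 30 around the metacommunity), each
sample a mixture m·pool + (1−m)·own-drift with m = 0.9 — within-layer
pairs come out far more similar than the Raup–Crick null. Dispersal
limitation: founder communities (15% of the pool, uniformly colonized,
fresh log-normal abundances) with m = 0.05 — pairs far more dissimilar
than null. Undominated: mild per-sample Dirichlet drift (concentration
5000) around the metacommunity; this value was calibrated once, at
design time, because unmodified multinomial draws are *more* similar
than the occupancy-weighted null (RC ≈ −0.8) while stronger drift
saturates at RC = +1 — the null band is narrow.

**Interdomain couplings.** 28 of 40 eukaryote OTUs per domain are coupled
to distinct prevalent bacterial OTUs: log abundance = per-OTU baseline ±
the partner's standardized log abundance + N(0, 0.3) noise, the sign
planted as 20 positive : 8 negative (P/N = 2.5). Uncoupled OTUs are
independent log-normal noise; eukaryote abundances are continuous, which
avoids rank ties. The network-recovery experiments use a 30-OTU neutral
bacterial table so that planted edges dominate the nominal false-positive
count (≈ 0.002 per tested pair at the |r| > 0.6 threshold): this is a
designed power choice, stated here rather than hidden.

**What passing these tests does and does not show.** The generator
emulates community-level structure — phylogenetically conserved habitat
preference, colonization lotteries, drift, monotone cross-domain
coupling, depth gradients — but not compositional sequencing noise,
chimeras, variable sequencing depth, or trophic structure beyond
pairwise monotone coupling. Recovery of planted regimes shows the
statistics and their nulls are implemented correctly and have power
under these conditions; it does not certify power or calibration on any
particular real dataset.

## 6. Validation problem sizes and numerical choices

The test suite validates: βNTI against exhaustive tip-permutation
enumeration on 4- and 5-tip trees (999 Monte-Carlo draws, 3-SE
agreement); RC-bray against exact enumeration of all null assemblies on
4- and 5-taxon pools; process recovery at full study scale (200 tips, 24
samples, J = 2000, 999 randomizations, pooled over three replicate
studies); the perturbation direction over 50 replicate studies at a
reduced scale (100 tips, niche 30, 2 layers × 4 samples, J = 1500, 199
randomizations); network P/N recovery over 50 seeds and false-positive
calibration against a label-permutation oracle over 30 seeds; and
bit-exact reproducibility of the full pipeline under a fixed seed. These
sizes are the package's chosen validation conditions; they keep the
whole suite near a minute on one CPU.

Numerical details worth knowing: Shannon entropy uses natural logarithm;
Faith PD uses the MRCA convention (root edge excluded; single-taxon
samples have PD 0); NMDS is Kruskal stress-1 via monotone regression
with 20 random starts plus a metric start; Spearman p-values switch to
exact permutation below n = 10 when there are no ties; the partial
Mantel statistic reports 0 (not NaN) in the fully-controlled degenerate
case where the conditioning matrix explains the second matrix entirely;
forward selection is greedy on AIC with collinear candidates dropped and
the empty model admissible; and every stochastic routine takes a seed,
with the pipeline expanding one global seed into named per-stage
substreams so adding a stage never perturbs earlier stages' randomness.

## 7. Known limitations

- βNTI has limited power for very small communities (few dozen taxa per
  sample against a small pool); masked pairs and wide null spreads are
  the symptom, not a bug.
- The Raup–Crick null conditions on richness and occupancy but not on
  the abundance distribution's shape; strongly non-log-normal real
  communities may sit off-centre even absent dispersal effects.
- Correlation networks are not compositional-aware (no SparCC/SPIEC-EASI
  here, by design); with few samples the |r| > 0.6 screen has
  non-trivial false-positive counts, which the calibration experiment
  quantifies rather than hides.
- PLS-PM on sample-pair observations inherits their non-independence;
  bootstrap intervals are accordingly optimistic and should be read as
  descriptive.
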