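---
title: "Methods: system-level analysis of BMI-associated gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: system-level analysis of BMI-associated gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bminet)
```

# Overview

`bminet` implements a system-level analysis of whole-blood gene expression in
relation to body mass index (BMI). The pipeline runs six stages on a
genes-by-samples log2 intensity matrix and a sample table:

1. **Preprocessing** — quantile normalization, empirical-Bayes batch
   adjustment, connectivity-based sample QC, stratum-median weight-group
   assignment, and selection of the top-expressed genes.
2. **Differential expression** — a moderated two-group t-test with
   empirical-Bayes variance shrinkage, BH adjustment, and an estimate of the
   number of non-null genes via the true-null proportion pi0.
3. **Co-expression networks** — soft-thresholded unsigned adjacency,
   topological overlap (TOM), module detection by tree cutting, eigengenes,
   module merging, and module–trait statistics.
4. **Differential connectivity** — percentile-thresholded edges in the
   normal-weight and overweight networks separately, the damped
   connectivity-change statistic delta-C, and hub-conversion calls.
5. **Three-way interactions** — entropy-based gene ranking, 2-D clustering of
   gene pairs, an information-theoretic synergy score, and control-gene
   attribution.
6. **Over-representation** — hypergeometric tests of gene modules against
   user-supplied GMT gene-set collections with BH adjustment.

Every stage is exposed as ordinary functions; `run_all()` ties them together
and writes TSV outputs. A synthetic-cohort generator (`sim_config()`,
`generate_cohort()`) plants known modules, a BMI-coupled module, rewired hub
genes and XOR-style synergy triples, so every stage can be validated against
ground truth.

# Models and statistics

## Weight groups

Each sample belongs to an ancestry stratum; the BMI cutoff defining
"overweight" is the *median BMI of the sample's own stratum*, which keeps the
two weight groups comparable in ancestry composition. The comparison is
strict: a BMI exactly at the stratum median is "normal", so within a stratum
at most `floor(n/2)` samples can be overweight. The strictness convention is
documented rather than prescribed by the study design, and is configurable
only in the sense that the rule is a small, isolated function.

## Moderated differential expression

For gene $g$ with pooled two-group variance $s_g^2$ on $d$ degrees of
freedom, the prior $(d_0, s_0^2)$ is fitted by matching moments of
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$: the excess of
$\operatorname{var}(e)$ over $\psi'(d/2)$ identifies $\psi'(d_0/2)$, and the
mean of $e$ identifies $\log s_0^2$. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ enters an ordinary
t-statistic with $d_0 + d$ degrees of freedom. When the observed spread of
log-variances does not exceed the theoretical chi-square spread, $d_0$ is
infinite and every gene uses $s_0^2$. The `prior_df` argument exposes the
two limits: `0` recovers the ordinary pooled t-test, `Inf` a fixed-variance
statistic. The test suite checks both limits in closed form and verifies the
full estimator against an independent reference implementation (limma) to
numerical precision.

Weight status is the only factor in the design, as in the study this package
operationalizes; general design matrices are out of scope.

## pi0, q-values and the non-null count

`estimate_pi0()` implements the fixed-lambda counting estimator
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ and, over the
default grid $\lambda = 0.05, \dots, 0.95$, a cubic smoothing spline
evaluated at the largest lambda (the q-value software's smoother). The
estimated number of non-null genes is $\lfloor m (1 - \hat\pi_0) \rfloor$;
with $m = 13{,}276$ and $\hat\pi_0 = 0.804$ this gives 2,602. q-values use
the running-minimum definition and reduce exactly to BH-adjusted p-values at
$\pi_0 = 1$.

## Co-expression networks

The unsigned adjacency is $a_{ij} = |\operatorname{cor}(x_i, x_j)|^\beta$
with the default soft power $\beta = 6$; `pick_soft_power()` can select
$\beta$ as the smallest power whose scale-free fit index reaches 0.8. The fit
index bins connectivities into ten equal-width bins and regresses
$\log_{10} p(k)$ on $\log_{10} \bar k$ — equal-width binning is the
convention of the reference WGCNA implementation; equal-count binning is
degenerate here because it forces a flat $p(k)$ by construction.

The topological overlap matrix is
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$
validated against a brute-force triple loop at $10^{-12}$.

**Module detection.** Genes are clustered by average linkage on
$1 - \mathrm{TOM}$ and the tree is cut by a simplified static rule: a fixed
dissimilarity cut at 0.96 (default), with clusters below `min_size = 10`
labelled unassigned. The rationale: TOM dissimilarities between unrelated
genes concentrate in a narrow band just below 1, so genuine modules complete
their merges well below it and a fixed cut separates the two regimes. Two
data-adaptive alternatives are available (`cut_method = "gap"`, the largest
jump in sorted merge heights, and `"quantile"`). A fixed quantile of merge
heights — a rule we initially tried — is *not* offered as the default
because most merges in a TOM dendrogram are background merges; any high
quantile of merge heights lands inside the background band and produces
either one blob or arbitrary splits. Module recovery on planted fixtures,
not label-parity with any particular reference implementation, is the
acceptance surface for this stage.

Modules whose eigengenes (first principal component of the standardized
module submatrix, sign-oriented along the module mean profile, unit
variance) correlate above $1 - 0.25$ are merged iteratively, mirroring the
conventional `mergeCutHeight = 0.25`.

## Differential connectivity

Within each weight group a TOM is computed over the identical gene universe,
and pairs above the group's own 99th-percentile TOM value are edges. For a
gene with connectivities $C_1$ (normal) and $C_2$ (overweight),
$$\Delta C = \frac{C_2 - C_1}{C_2 + C_1 + s},$$
where the pseudo-count $s$ damps small-degree noise. The package defaults
$s$ to the mean gene connectivity of the *combined* (all-sample) network —
the analogous study-specific constant was 45.47, which is not portable, so
the data-derived default is used and any fixed value can be supplied.
$\Delta C > 0.5$ (strict) calls a non-hub-to-hub conversion in the
overweight network, $\Delta C < -0.5$ the reverse; values at the boundary
are stable. Network 1 is the normal-weight network, so positive $\Delta C$
means connectivity gained in overweight samples.

## Three-way (synergy) interactions

Genes are ranked by the conditional entropy of weight status given the
gene's median-dichotomized state, in *descending* order: genes whose
individual high/low state carries no information about status come first,
which is exactly the candidate set for purely synergistic (XOR-like)
effects. Because the dichotomized statistic is discrete, exact ties are
common (with 42/42 groups, a perfectly balanced 2x2 table arises for roughly
one gene in six); ties are broken by the gene's absolute Pearson correlation
with status — the continuous analogue of the same criterion — and then by
gene id.

Each pair among the top 100 ranked genes is embedded in 2-D (each gene
standardized), clustered by average linkage, and the tree is cut at 0.02 of
its maximum merge height. The synergy of the pair is
$$\mathrm{syn} = \frac{I(\mathrm{cluster}; \mathrm{status})
 - I(a_{\mathrm{bin}}; \mathrm{status}) - I(b_{\mathrm{bin}}; \mathrm{status})}
{H(\mathrm{status})} \le 1 ,$$
with plug-in estimates. Before any information statistic is computed,
clusters smaller than `min_cluster_size = 5` samples are pooled into a
single background pool. This guard is essential: at a 2% relative cut,
unstructured data shatters into near-singleton clusters, and the plug-in
$I(\mathrm{cluster}; \mathrm{status})$ of a singleton clustering equals
$H(\mathrm{status})$ — every noise pair would score a synergy near 1. With
pooling, null synergy is non-positive (verified over hundreds of null pairs)
while the balanced XOR construction still attains exactly 1.

Pairs with synergy above 0.9 proceed to control-gene attribution: each
candidate among the remaining top-ranked genes is dichotomized at its
median, and its purity is $I(\mathrm{cluster}; x_{\mathrm{bin}}) /
H(x_{\mathrm{bin}})$ — 1 precisely when every cluster is filled with a
single up/down state of the candidate. The best candidate is attributed if
its purity reaches 0.5.

## Over-representation

Plain hypergeometric upper-tail tests of a query list against each set of a
GMT collection, with every set first intersected with the supplied
background (the expressed genes, by convention) and BH adjustment across
sets. No ontology-aware (conditional) testing is attempted.

# The synthetic cohort generator

`sim_config()` defaults describe the package's standard validation cohort,
chosen once to mirror the data regime of the motivating study and the
detectability limits of its methods at that size:

* **2,000 genes x 84 samples**, three ancestry strata of 28 samples with
  median BMIs 24.83, 29.51 and 23.46 kg/m^2 (realistic stratum medians) and
  within-stratum BMI spread of 4 kg/m^2. Even strata sizes make the
  stratum-median rule split each stratum exactly in half, giving 42/42
  weight groups.
* **Five modules of 45, 40, 32, 27 and 22 genes**, realized as latent-factor
  blocks (`gene = 0.82 * factor + 0.45 * noise`). Module sizes are chosen so
  that within-module pairs amount to ~1.16x the number of edges a
  99th-percentile cutoff admits among 700 expressed genes. The edge cutoff
  then falls at the lower edge of the within-module TOM distribution:
  essentially all module pairs are edges in both group networks (stable
  per-gene connectivity), and background genes are locked out of the edge
  list, which is what makes the +/-0.5 hub-conversion threshold a
  low-false-positive decision rule at n = 42 per group. Planting *larger*
  modules than the edge budget tolerates makes per-gene connectivity a
  lottery on the cutoff boundary — a property of percentile-thresholded
  networks worth knowing about in real data as well.
* **Module 1 drives BMI** with correlation 0.6 between its factor and the
  within-stratum BMI deviation.
* **20 rewired hubs**: module genes whose loading is 0.95 inside one weight
  group and exactly 0 in the other — the ground truth for hub-conversion
  calls in both directions.
* **Five XOR synergy triples** planted on genes outside the modules:
  overweight samples are split evenly between the (high, high) and
  (low, low) quadrants of the pair, normal samples between the mixed
  quadrants, so each gene's marginal state is independent of status while
  the joint pattern determines it. The control gene's state matches gene
  A's state — the only marginally silent choice that still fills every
  quadrant cluster with one up/down state. A consequence is that the
  detector also reports the mirrored triple (X, B, control = A); recovery is
  scored on exact matches of pair and control gene against the planted
  table, and mirrors are additional rows, not errors. Quadrant splits are
  randomized independently per triple. Triples are planted after the batch
  distortion so the planted geometry is exactly what the analysis sees, with
  state amplitude 1.2 log2 units and within-state jitter 0.01.
* **Two batches** distorting each gene by a random shift (sd 0.3) and scale
  (log-sd 0.1); gene baselines place structured genes high enough that the
  top-35% expressed filter retains them, as it retains genuinely expressed
  genes on a real array.

All randomness flows from the single `seed` through one seeded generator;
identical configurations produce byte-identical fixture bundles
(`write_fixture_bundle()`).

## What the generator does and does not emulate

It emulates modular co-expression with controllable eigengenes, a
trait-coupled module, batch location/scale distortions, ancestry strata with
different BMI medians, group-specific hubs, and exact XOR synergy. It does
*not* emulate probe-level microarray artifacts, heavy-tailed intensity
distributions, correlated module factors, ancestry genotypes, or
missing-data mechanisms beyond optional NA injection in clinical traits.
Passing the recovery suite therefore demonstrates that the algorithms
recover the structures they claim to recover under the stated model — not
that real whole-blood data meet those assumptions.

Recovery tests run on the generated matrix (plus the expressed-gene filter)
rather than on quantile-normalized, batch-adjusted data. The generator
already produces a common-scale matrix, and quantile normalization couples
every gene's mapped values to the rank volatility of the strongly co-varying
module genes, which audibly blurs planted geometry — an interesting QN
property, but one that would make the recovery tests measure the
preprocessing interplay rather than the stage algorithms. Normalization and
batch adjustment have their own contract tests (including a cross-check
against the reference ComBat implementation), and `run_all()` exercises the
full chain end to end.

# Numerical choices and degenerate inputs

* Quantile normalization averages reference quantiles over tied ranks; it is
  exactly idempotent on tie-free data. With ties, re-application can shift
  values at the order of the tie spacing (the reference itself changes), a
  property shared by the standard implementations.
* The expressed-gene count rounds half away from zero
  (0.35 x 13,276 = 4,646.6 -> 4,647); ranking ties break lexicographically.
* Batch adjustment with a single gene degenerates to per-batch
  standardization (the EB moment estimators need multiple genes).
* Zero-variance genes: an error in adjacency construction (they have no
  correlation), a floored variance with a warning in the moderated t, and an
  "uninformative" fallback in conditional entropy.
* `trigamma_inverse` uses the conventional Newton recursion with asymptotic
  guards at both ends.
* Merge heights in `hclust` trees are clamped to be non-decreasing before
  `cutree` to guard against float-level inversions on degenerate TOMs.
* Problem sizes in tests and the acceptance script (2,000-gene cohorts, 20
  null replicates at 200 genes, 10^4 uniform p-values) are the package's
  validation sizes, chosen to make every stochastic criterion decisive at
  comfortable margins.

# Known limitations

* The two-group moderated t supports no covariates or general designs.
* Module detection is a simplified static tree cut, not the hybrid dynamic
  algorithm of the WGCNA package; agreement with WGCNA labels is not a goal.
* The synergy stage is a concrete plug-in realization of the cluster-based
  synergy idea; bit-for-bit parity with existing synergy-analysis tools is
  not a goal, and constants (tree height 0.02, top 100 genes, synergy 0.9,
  purity 0.5, pooling size 5) are all configurable.
* Enrichment is plain over-representation; DAG-aware conditional tests and
  external resources (pathway databases, PPI networks, TFBS scans) are out
  of scope.
* The study-specific headline counts that depend on the original microarray
  cohort (seven DE genes, 21 modules and their colors, 246/286 hub
  conversions, 28 triples) are not reproduction targets; the package's
  acceptance surface is the planted-truth recovery documented above.
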