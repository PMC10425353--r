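---
title: "Methods behind bowerbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind bowerbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowerbrain)
```

# The problem

Male Lake Malawi cichlids of castle-building lineages pile sand into
elevated structures ("castles") that serve as territories and mating sites.
bowerbrain implements an analysis chain that links this recently evolved
behavior to brain cell populations from four directions:

1. **Behavior quantification.** Depth-sensor maps of the sand surface and
   action-recognition event streams are reduced to a single Bower Activity
   Index (BAI) per male.
2. **Activity signatures in single nuclei.** Immediate early genes (IEGs)
   peak in expression roughly an hour after neuronal excitation; a
   per-nucleus IEG score over a panel of co-induced genes flags recently
   active populations, and a multi-model mixed-model competition asks
   whether building, courtship quivering, or gonadal state explains that
   score.
3. **Genomic divergence.** Windowed Weir–Cockerham F\_ST between
   pit-digging, castle-building, and rock-dwelling species localizes
   castle-associated divergence; genes near doubly divergent windows
   ("castle-divergent genes", CDGs) are carried into expression analyses,
   together with estrogen response element (ERE) annotations.
4. **Co-expression structure.** A signed-adjacency medoid clustering finds
   tight CDG modules, and permutation machinery relates module expression
   to glial quiescence states.

Every stage is exercised end-to-end on synthetic data whose generator is a
first-class, tested module.

# Behavior: depth maps and the Bower Activity Index

`cleanDepth()` fills missing regions of at most `max_hole_px` pixels by
nearest-neighbor interpolation and smooths with a Gaussian kernel
(`smoothing_sigma`, default 1 px). The published pipeline describes
smoothing and interpolation without specifying the algorithm, so both are
configurable; the Gaussian is implemented as a mask-normalized separable
convolution, which preserves constants, reduces to plain convolution away
from edges, and leaves unfillable holes missing.

`detectBowerRegions()` grows connected components of pixels whose elevation
change strictly exceeds `height_threshold` (0.2 cm) in one direction and
keeps components of at least `min_pixels` (1000, about 10 cm²).
4-connectivity is the default reading of "contiguous"; 8-connectivity is a
flag. Both thresholds are strict, matching the field convention of "more
than 0.2 cm" and "one thousand or more" (the pixel-count bound is
inclusive, the height bound exclusive). Region volumes are divided by the
cubed standard length (`volume / SL^3`) because larger males move more sand
per scoop.

`computeBAI()` fits ordinary least squares of (size-adjusted) depth change
on predicted building events across subjects, projects every subject
orthogonally onto the fitted line, and reports the Euclidean distance along
the line from the projection of the anchor (0 events, 0 depth change),
clamped at zero below the anchor. Axes are kept in raw units; no
standardization is applied (the alternative is a documented open choice).
BAI is therefore equivariant under common rescaling of both axes.

# The IEG screen and panel scores

`anchorCoexpressionScreen()` generalizes marker finding to an anchored
co-expression screen. For each of three anchor IEGs (c-fos, egr1, npas4)
and each fine-grained cluster with at least `min_positive_nuclei`
anchor-positive *and* anchor-negative nuclei, nuclei are split by anchor
detection and every candidate gene expressed in at least `min_pct` (1/57)
of either split is tested with a two-sided rank-sum test. A gene passes for
an anchor when it is detected in a strict majority of that anchor's
*eligible* clusters and upregulated (positive shift, p < 0.05) in a strict
majority of those detected clusters; the final panel intersects the three
per-anchor lists. Two deliberate interpretations: the majority denominator
counts eligible clusters (counting all clusters is available via
`majority_denominator = "all"`), and the detection rule uses
at-least-one-group semantics. The rank-sum test uses a tie-corrected normal
approximation with continuity correction, switching to the exact
distribution when both splits have fewer than 20 nuclei and no ties.

`panelScore()` counts detected panel genes per nucleus (0..m). The same
operation serves the IEG score (m = 25), proneurogenic scores,
quiescence/cycling/differentiation state scores, and CDG module scores.

# The model competition

Because building, quivering, and gonadal state are correlated in breeding
males, no single regression can attribute an expression signal to one of
them. The competition fits seven fixed-effect specifications — every
pairwise and three-way combination of building (as continuous BAI in three
models and as the binary condition in three), log-quivering, and GSI — each
with nested random intercepts, and declares a focal effect significant only
if (1) its raw p-value is below 0.05 in *every* model containing it and (2)
the FDR-adjusted harmonic mean p across those models is below 0.05
(`runCompetition()`, `adjustCompetition()`).

`harmonicMeanP()` defaults to the raw harmonic mean, which is what enters
the dual rule; the asymptotically exact transform (through the Landau-type
null distribution of the reciprocal harmonic mean, evaluated by numerical
integration of the stable-density tail) is exposed via
`mode = "asymptotically_exact"` for use as a standalone p-value.

## Estimation

The IEG-score model is a logit-link beta-binomial regression
(`fitBetaBinomialMixed()`). By default nuclei are aggregated to one
overdispersed binomial observation per subject — the total number of
detections out of `nuclei x m` trials — with pool, batch, and pair random
intercepts; the beta-binomial dispersion absorbs between-subject and
between-nucleus heterogeneity. A per-nucleus `method = "nuclei"` keeps the
full batch/pool/subject nesting. Fits use restricted maximum likelihood
(Laplace approximation, glmmTMB).

Wald tests use a *t* reference with containment-style degrees of freedom:
for each covariate, the number of levels of the coarsest grouping factor
within which it is constant, minus the number of fixed-effect parameters.
This matters because telencephala are pooled by condition before library
preparation, so the binary condition contrast is replicated at the level of
ten pools, not 38 subjects; a normal-reference Wald test is visibly
anticonservative in that design, and the containment correction restores
the nominal error rate (the test suite checks the empirical type-I rate of
the building term against the 3–8% band at the study's size: 19 pairs,
about 200 nuclei per subject, 200 simulation replicates). Random-effect
variances that collapse to the boundary trigger a refit with the degenerate
terms removed; data with no overdispersion at all degenerate the
beta-binomial likelihood itself, in which case the binomial limit is fitted
and labeled as such.

Gene-level counts use the same machinery with a negative-binomial family,
log size-factor offsets (`sizeFactors()`: library-size by default,
median-ratio optional), and per-gene method-of-moments dispersion with a
log-linear trend shrink (`estimateDispersion()`); genes not observed in
every pair are refused, mirroring the upstream filter. The Poisson limit
stands in at the zero-dispersion boundary.

Cluster-proportion shifts (`proportionCompetition()`) treat each nucleus as
a Bernoulli trial — against all nuclei for coarse clusters, against the
parent cluster's nuclei for fine clusters — aggregate per subject, and fit
a binomial mixed model (condition, GSI, quivering; random subject intercept
as an overdispersion term), BH-adjusting the building p-values across
clusters. BH is used everywhere multiplicity arises in this package.

`laggedAssociationProfile()` replaces the behavior covariate with each
temporal bin's event count in turn and records the absolute Wald *t* of the
focal term, tracing when the behavior driving an expression signal
occurred. With 30-minute bins sliding by 15 minutes, a transcript program
lagging behavior by ~60 minutes peaks in the 45–75 minute bin.

# Gene-set enrichment with an expression-matched null

`normalizedSetScore()` divides the per-nucleus count of detected set genes
by the number of all detected genes, removing sequencing-depth leverage.
`clusterZTest()` compares nuclei inside a cluster against all others with a
two-sample unpooled-variance Z (sample SDs standing in for population SDs;
a one-sample variant of the published description is conceivable — the
two-sample form is the documented choice), plus Cohen's d on the pooled SD.

The permutation gate (`matchedRandomSets()`, `permutationEnrichment()`)
guards against expression-level confounding: genes are ranked by total
counts (ties broken by identifier), each set gene gets a pool of its 100
nearest-ranked non-set genes, and each of 10,000 random lists draws one
gene per pool. A cluster is flagged only when the BH-adjusted Z p-value is
below 0.05 *and* the observed d exceeds at least 95% of the random-list d
values. `categoryEnrichment2x2()` reports the sample odds ratio `ad/bc`
and a two-sided Fisher exact p for 2x2 category enrichment.

# Genomic divergence and ERE annotation

`siteFilter()` keeps biallelic polymorphic sites with genotype missingness
below 50% in both groups ("50% or more" excludes). `weirFstWindows()`
computes the Weir–Cockerham (1984) variance components a (among
populations), b (among individuals within populations), and c (within
individuals) per site, treating species as diploid sampling units, and sums
them over non-overlapping 10-kb tiles: the windowed estimate is the ratio
of sums, never a mean of per-site ratios. Slightly negative windows are
legitimate. `castleDivergentWindows()` intersects the pit-vs-castle and
rock-vs-castle contrasts with a strict 0.20 threshold on both.
`genesNearFeatures()` reports genes strictly within 25 kb of a retained
window (distance 0 when overlapping).

`ereScan()` searches for the palindromic inverted-repeat ERE
`AGGTCA-NNN-TGACCT` (15 bp). The half-site description names only
`AGGTCA`; the inverted repeat is the canonical functional element, so it is
the default and a direct-repeat mode sits behind a flag. Because the motif
is its own reverse complement up to the spacer, one strand suffices.
Ambiguity codes never match, including in the spacer. Sites are assigned to
their nearest gene (ties: lower start coordinate, then identifier) and
classified intragenic / promoter (within 5 kb upstream of the strand-aware
start) / distal (< 25 kb) / unassigned.

# Co-expression modules

`buildCoexpressionModel()` computes Pearson correlations of candidate genes
on `log1p` library-size-normalized expression (the exact normalization
upstream of the published correlation matrix is unspecified; this is the
package's choice), picks the lowest soft power whose scale-free fit index
reaches 0.90 (`pickSoftPower()`; index = signed R² of log10 p(k) on log10 k
over 10 connectivity bins), forms the signed adjacency
`((1 + cor)/2)^power`, uses it directly as the topological overlap matrix,
and clusters the dissimilarity `1 - adjacency` with
`pamWithSilhouette()`. k is chosen to maximize the mean silhouette width
over `2..min(10, n-1)` — "all possible k" is not computable literally —
with ties to the smallest k.

One departure from the textbook algorithm: the PAM build+swap heuristic is
only locally optimal and demonstrably misses the global medoid optimum on a
noticeable fraction of even six-point instances. When the number of medoid
subsets is small (at most 5000), `pamWithSilhouette()` therefore finds the
exact optimum by enumeration; the deterministic heuristic (no random
restarts, hence seed-free) is used for larger problems.

`moduleStrength()` runs Welch t-tests of silhouette widths and of
within-module versus module-to-outside correlations.
`moduleScoreAssociation()` correlates the module score with a reference
score (e.g. a quiescence score) and builds the null by independently
permuting each module gene's expression across nuclei, with an
add-one-corrected two-sided p. `tfCoexpressionScreen()` ranks transcription
factors by correlation with the module score.

# The synthetic-data generator

`simulationConfig()` defaults encode the study conditions the analyses
assume: 19 building/control pairs; pools of 3–4 same-condition subjects
(condition-pooled, which is why the condition contrast is replicated at the
pool level) with paired pools sharing a batch; a 25-gene IEG-like panel
whose first three members are the anchors; nested random intercepts;
beta-binomial overdispersion of panel detection; a Gaussian lag kernel
peaking 60 minutes before collection; pit/castle/rock groups of 11/9/7
species with 10-kb windows; and a motif-free genomic background (by
rejection) for planted EREs.

Specifics worth knowing:

* Nuclei-per-subject totals are Dirichlet-multinomial around equal shares
  (concentration 50), mimicking pools of size-matched telencephala.
* Panel genes share a per-nucleus activity propensity: the detection
  probability is logit-linear in the subject's behavior covariates plus
  nested random intercepts, then beta-distributed per nucleus with
  intra-nucleus correlation `rho`. The default `rho = 0.05` models residual
  overdispersion for score regressions; screen-recovery simulations use
  `rho = 0.3`, reflecting the strong co-induction that makes a gene panel
  discoverable in the first place.
* Background genes are negative-binomial with lognormal library-size
  offsets. A planted module rides a shared latent factor whose loading is
  calibrated deterministically (Gauss–Hermite over the factor, exact
  negative-binomial moments) so that the configured correlation is
  approximately realized on the observed `log1p` scale rather than on the
  latent scale. When a module is planted, all candidate genes are drawn
  moderately expressed with a weak shared background factor
  (`background_cor = 0.15`), emulating a candidate set of well-detected
  genes with common cell-state covariation — without that cohesion the
  background would scatter arbitrarily between medoids.
* Planted marker sets multiply the detection probability in one chosen
  cluster (e.g. the 2x sets used in enrichment power checks).
* Divergent windows push the castle-group allele frequency to 0.95 versus
  0.05 elsewhere; missingness is per-site, per-species.
* Every generator restores the RNG state and is byte-deterministic in the
  seed.

What the generator does **not** emulate: UMI-level error or ambient RNA,
doublets, cluster-specific expression programs beyond planted marker sets,
linkage disequilibrium between variant sites, spatial structure, and
selection of the panel itself from real co-expression (the screen is tested
on planted programs). Passing tests therefore demonstrate that the
statistical machinery behaves as designed under its own assumptions, not
that those assumptions hold in any particular tissue.

# Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as
follows: the null calibration and effect-recovery checks of the building
term run 200 replicates at 19 pairs x ~200 nuclei; enrichment power and
module recovery use 20 seeds (1000 and 500 random lists for the
permutation gates); F\_ST and bower-detection oracle comparisons use 100
randomized instances; the strict lag-recovery claim (argmax bin = the
45–75 minute bin) runs 50 replicates at study-scale nuclei counts, with a
lighter 12-replicate overlap property alongside, and the disentanglement
property drives the planted effect through the continuous BAI covariate.
Degenerate inputs are handled explicitly: all-zero scores are a
boundary error, empty nuclei are excluded from normalized scores with a
warning, clusters with singleton membership are skipped, and zero-variance
windows are omitted with a flag.

# Known limitations

* The beta-binomial subject aggregation trades nucleus-level resolution for
  speed and stability; the per-nucleus path is exposed but slower.
* Size factors and dispersions are simplified relative to pooled
  deconvolution and gamma-Poisson trend fitting; both are documented
  substitutions behind the same interfaces.
* The containment-df t reference is a conservative small-sample correction,
  not a Satterthwaite/Kenward–Roger approximation.
* `directionBiasTest()` is a plain Yates-corrected 1-df goodness-of-fit
  against an even up/down split; intended for descriptive use.
* Connection weights for the communication analyses are inputs; their
  computation is out of scope.
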