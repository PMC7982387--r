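---
title: "Methods: multilocus phylogeography and symbiotic effectiveness of chickpea rhizobia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilocus phylogeography and symbiotic effectiveness of chickpea rhizobia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizogeo)
```

## The problem this package addresses

Chickpea is nodulated almost exclusively by *Mesorhizobium*. Collections of
chickpea-nodulating strains are routinely characterized by multilocus
sequence analysis (MLSA) of housekeeping genes, assigned to genospecies by
similarity to published reference strains, and screened in greenhouse
trials for symbiotic effectiveness. The scientific questions are: how much
genetic diversity does a regional collection hold relative to a reference
population, is that diversity structured in space (isolation by distance,
elevation effects), and does taxonomy or geography predict symbiotic
performance?

`rhizogeo` implements that entire analysis chain as tested, reusable
functions, together with a seeded generator that produces synthetic
datasets with the statistical structure the analysis assumes, so every
stage can be validated end to end without access to the original
sequences.

## The genetic-distance hierarchy

Diversity is quantified at three levels of genomic hierarchy.

**Nucleotide level.** For strains $i, j$ aligned over $L$ columns, the
p-distance is the proportion of differing sites among columns where both
sequences carry an unambiguous base (pairwise deletion; a
complete-deletion switch is provided). The Tamura–Nei (1993) distance
corrects for multiple hits with separate purine-transition ($P_1$),
pyrimidine-transition ($P_2$) and transversion ($Q$) proportions:

$$d = -\frac{2 g_A g_G}{g_R}\ln w_1 - \frac{2 g_T g_C}{g_Y}\ln w_2
      - 2\Big(g_R g_Y - \frac{g_A g_G g_Y}{g_R} - \frac{g_T g_C g_R}{g_Y}\Big)\ln w_3$$

with $w_1 = 1 - \frac{g_R}{2 g_A g_G}P_1 - \frac{Q}{2 g_R}$, $w_2$
analogous for pyrimidines, and $w_3 = 1 - \frac{Q}{2 g_R g_Y}$. Base
frequencies are pooled over the whole alignment rather than per pair:
per-pair frequency estimates are unstable at the sequence lengths involved
(hundreds of base pairs), and pooling makes distances comparable across
pairs. Pairs for which any $w_k \le 0$ (saturation) are flagged undefined
rather than silently dropped. An optional gamma rate-heterogeneity
correction with user-supplied shape $\alpha$ replaces $-c\ln w$ by
$c\,\alpha(w^{-1/\alpha}-1)$; the plain distance is the default because no
shape estimate is assumed to exist.

**Haplotype (locus) level.** Within each locus, byte-identical sequences
(gaps significant) share a haplotype; the allele-sharing distance between
two strains is the fraction of loci at which they carry different
haplotypes, so values lie on the grid $0, 1/L, \dots, 1$. Treating gaps as
characters keeps haplotype identity deterministic and matches allele
semantics on pre-aligned loci.

**Species level.** Strains are assigned to genospecies by average
nucleotide identity (ANI $= 1 -$ p-distance) to a labelled reference
panel; the species-level distance is the 0/1 indicator of different
genospecies. The default assignment threshold is ANI $\ge 0.95$, motivated
by reported within-genospecies ANI floors for *Mesorhizobium*
housekeeping MLSA (roughly 95–99%); it is a tunable argument.

Site statistics mirror the standard alignment summary: a column with any
gap or ambiguity code is *excluded*; among fully unambiguous columns, one
observed state is *conserved*; a variable column with at least two states
each in at least two sequences is *parsimony-informative*, otherwise a
*singleton*. Exclusion of gapped/ambiguous columns is the package's
deterministic rule; published tables produced by other software can use
slightly different exclusion rules, so exact reproduction of such tables
is not guaranteed (the identities
`variable = PI + singletons` and `conserved + variable + excluded = length`
always hold).

## Diversity indices and the bootstrap comparison

Genospecies compositions are summarized by the Shannon index
$H = -\sum p_i \ln p_i$ and the Gini–Simpson index $D = 1 - \sum p_i^2$
(computed through `vegan`). To compare an observed sample against a
reference population, the package draws $B$ samples of size $n$ with
replacement from the reference labels (defaults $B = 10{,}000$, $n = 39$)
and reports the permutation-style lower-tail p-value
$p = (1 + \#\{H_b \le H_{obs}\})/(B+1)$. The lower tail is the default
because the scientific question is whether the observed sample is *less*
diverse than the reference; a two-sided option exists. Categories absent
from a resample are ignored rather than erroring, since rare categories
routinely drop out of finite draws. The generator seed is recorded in the
result.

## Spatial inference

**Mantel and partial Mantel tests.** The Mantel statistic is the Pearson
correlation of the strict lower triangles; the null distribution comes
from simultaneous row/column permutation of the first matrix (default
9,999 permutations, two-sided p with the $+1$ correction). The partial
statistic is the first-order partial correlation
$r_{XY\cdot Z} = (r_{XY} - r_{XZ} r_{YZ})/\sqrt{(1-r_{XZ}^2)(1-r_{YZ}^2)}$,
with significance from permuting $X$ and recomputing the partial
statistic (Smouse–Long–Sokal scheme). A covariate perfectly correlated
with either matrix is rejected as degenerate. Two-sided testing is the
default because biogeographic Mantel tables legitimately contain negative
correlations; one-sided flags are exposed.

**PCoA.** Principal coordinates are obtained by Gower double-centering of
$-\tfrac12 D \circ D$ and eigendecomposition; axes with positive
eigenvalues are kept and scaled by $\sqrt{\lambda}$. Negative eigenvalues
(non-Euclidean inputs such as the allele-sharing matrix) are reported, not
corrected: corrections change distances and should be an explicit user
decision. Eigenvalues within $10^{-9}\,\max|\lambda|$ of zero are treated
as null axes.

**Coordinate regression.** Each genetic principal coordinate is regressed
by ordinary least squares on the leading geographic principal coordinates
(default two, standing in for latitude/longitude along a roughly linear
transect) and altitude, with per-term sequential-ANOVA F tests. Three
genetic axes are analysed by default: with four genospecies clusters the
between-cluster structure spans three axes, and in practice
altitude/geography associations appear on the second and third axes as
often as the first because small clusters carry little eigen-mass.

**Sliding-window distance decay.** Windows of 40 km width are moved at
10 km steps across the range of inter-strain geographic distances. In each
window holding at least one pair, one pair is sampled uniformly and its
nucleotide and haplotype distances are recorded; a baseline of equally
many pairs drawn irrespective of distance provides the comparison. Empty
windows are reported as empty rather than dropped, so profiles from
different datasets align. Single-pair sampling makes individual profiles
deliberately noisy (that is the design being emulated); an `exhaustive`
mode averaging all within-window pairs is provided for variance reduction.
The `window_decay_correlation()` summary is the Spearman correlation of
window midpoint with the sampled distance.

## Greenhouse symbiosis analysis

The trait table is a balanced randomized complete block design (strains
$\times$ replicates, default $r = 3$) with nodule number, nodule dry
weight (mg), shoot dry weight (g) and root dry weight (g).

- **Symbiotic response** is the first principal component of the scaled
  (zero-mean, unit-variance) trait matrix, sign-oriented so the nodule
  dry-weight loading is positive. Scaling makes scores invariant to
  affine changes of trait units.
- **Symbiotic performance** is shoot dry weight itself (plant dry
  matter). The two are deliberately distinct outputs.
- **Variance components** use the closed-form expected-mean-squares
  solution for the balanced two-way design without interaction:
  $\hat\sigma^2_{strain} = (MS_{strain} - MS_{error})/r$, with the exact
  $F = MS_{strain}/MS_{error}$ on $(s-1, (s-1)(r-1))$ df. Negative moment
  estimates are truncated to zero and flagged. Unbalanced data is
  rejected rather than approximated — the closed form is exact only for
  the balanced design, and silently switching estimators would change the
  test. Mean squares below $10^{-12}\,\overline{y^2}$ are treated as
  exactly zero so constant responses yield an undefined (flagged) F
  instead of a floating-point noise ratio.
- **Dunnett-style contrasts** against the uninoculated control estimate
  the familywise-adjusted p-value by Monte Carlo: the max-$t$ null is
  sampled (default $10^5$ draws) using a shared control draw and a shared
  $\chi^2$ variance draw, which induces the Dunnett correlation
  structure; Monte-Carlo error is $O(1/\sqrt{n_{mc}})$. One-sided
  "greater" is the default (is the strain better than no inoculation?).
  Reported adjusted p-values are clamped from below at the analytic
  per-comparison p, an identity the exact Dunnett adjustment satisfies
  and Monte-Carlo noise can otherwise violate.
- **Genospecies contrasts** report a two-sided Welch t-test and a
  one-sided Wilcoxon rank-sum test (exact for group sizes $\le 15$
  without ties), plus the percent difference
  $(\bar y_A - \bar y_B)/\bar y_A \times 100$.

## What the synthetic generator emulates

`simulation_config()` defaults encode the study conditions: 39 strains in
four genospecies clusters of 26/8/2/3; three housekeeping loci of
1045/390/307 bp (1742 bp concatenated); a GC-rich base composition and a
2:1 transition:transversion kernel; a ~400 km SW–NE sampling transect
with 16 sites; clusters II–III confined to the south-western fifth of the
transect (cluster III to a single site); cluster IV present only at two
sites above 2400 m; within-cluster divergence 0.005 and between-cluster
divergence 0.03 substitutions/site; and a balanced 3-replicate greenhouse
trial with an uninoculated control that has zero nodulation and a 15%
biomass deficit. Within-group coefficients of variation (residual 20%,
block 5%) are in the range typical of Leonard-jar trials.

Isolation by distance uses a *gradient block* scheme: every strain
carries exactly `round(0.005 * 1742) = 9` substitutions relative to its
cluster ancestor; a fraction `ibd_strength` (default 0.8) of them is
taken from a contiguous block of cluster-specific candidate positions
whose offset slides with the strain's transect position, the rest are
private random substitutions. Nearby strains therefore share mutations
and genetic distance grows with geographic separation, while the distance
of every strain to its cluster ancestor — and hence ANI-based genospecies
recovery — is unaffected by `ibd_strength`. At `ibd_strength = 0` the
design is exchangeable, which is what the type-I-error calibrations use
(together with `spatial_structure = FALSE`, which lifts the geographic
cluster restrictions and the elevation rule). Local clonality
(`clonal_rate`, default 0.5) lets strains repeat their site founder's
haplotype, which is what gives the haplotype level its short-range
homogeneity.

What the generator does *not* emulate: recombination and horizontal gene
transfer (the real system shows HGT of symbiosis genes), indels
(alignment columns are never created or destroyed; gaps can be injected
at random positions to exercise pairwise deletion, but they do not model
indel evolution), rate variation among sites, and sequencing error.
Passing tests therefore demonstrate that the statistics recover the
structure they assume, not that the assumptions hold for any particular
real collection.

## Numerical and design choices

- Earth radius fixed at the IUGG mean 6371.0088 km for reproducible
  geographic distances.
- Permutation p-values always use the $+1$ correction, so
  $p \ge 1/(n_{perm}+1)$.
- All stochastic functions accept a seed, restore the caller's RNG state,
  and record the seed in their output; identical seeds give byte-identical
  results.
- Strain-set mismatches between loci are errors, never silent
  intersections; subsetting is always an explicit caller decision.
- Distance-matrix constructors enforce symmetry, zero diagonal and
  non-negativity on every construction.

## Problem sizes used in the test suite

The shipped tests calibrate type-I error for the Mantel, partial Mantel,
coordinate-regression and variance-component tests over 1,000 null
simulations each (99 permutations per simulation) and the Monte-Carlo
Dunnett familywise error over 200 simulations of 10 treatments at 4,000
null draws; recovery checks use 200 generator runs for the
distance-decay and Mantel power properties and 500 replicates for
variance-component recovery at $s = 30$, $r = 3$. These sizes give
99%-binomial-CI resolution around the nominal $\alpha = 0.05$ while
keeping the full suite around two minutes on one CPU.

## Known limitations

- TN93 distances are undefined for saturated pairs; downstream PCoA and
  Mantel steps require a complete matrix, so saturated datasets must be
  handled (e.g. via p-distance) by the caller.
- The variance-component estimator is restricted to balanced designs by
  construction.
- Genospecies assignment is nearest-reference only; it does not discover
  clusters absent from the panel (such strains surface as "unassigned").
- The sliding-window resampler assumes a roughly linear sampling transect
  when interpreting window midpoints; two-dimensional sampling designs
  dilute the interpretation of a single distance axis.
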