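---
title: "Ordering astrocyte nuclei along a reactivity trajectory: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering astrocyte nuclei along a reactivity trajectory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Astrocytes respond to neurodegenerative pathology by shifting from a
homeostatic to a reactive transcriptional state. In single-nucleus RNA-seq
of post-mortem cortex this shift is not a discrete cluster boundary but a
continuum: protoplasmic (gray-matter) astrocytes spread along an axis from
high expression of homeostatic genes (synaptic adhesion and ERBB-family
signaling, e.g. *NRXN1*, *NRG3*, *GPC5*, *ERBB4*) toward canonical
reactivity markers (*VIM*, *CHI3L1*). `astrotraj` implements the full
analysis around that idea:

1. **QC and normalization** — drop genes detected in fewer than 30 nuclei
   and nuclei expressing unusually many genes (a doublet symptom), scale
   each nucleus to a common depth, transform by `ln(1 + x)`.
2. **Clustering and annotation** — PCA/kNN neighbor graph, Leiden
   modularity clustering across a resolution sweep, per-cluster Wilcoxon
   rank-sum markers with Benjamini-Hochberg correction, marker-panel
   labeling with doublet panels taking precedence, and a Sankey-style
   cluster-flow table across resolutions.
3. **Diffusion pseudotime** — an adaptive-bandwidth Gaussian kernel on the
   kNN graph, the top nontrivial eigenpairs of its transition matrix, a
   root nucleus at the homeostatic extreme, and pseudotime as the distance
   in `psi_i * lambda_i / (1 - lambda_i)` space from the root, scaled to
   [0, 1].
4. **Trajectory regression screen** — rank-uniformize pseudotime, regress
   every gene's expression on it by OLS, and call a gene dysregulated when
   `|beta| > 0.1`, `R^2 > 0.1`, and Bonferroni-corrected `p < 0.05`.
5. **Pathology mixed model** — per-nucleus pseudotime against donor-level
   amyloid, tau, *TREM2* R47H, *APOE* genotype, and age, with a random
   intercept per donor.
6. **Enrichment statistics** — Fisher and chi-squared primitives for
   signature overlaps (mouse-model signatures via a homology map),
   transcription-factor enrichment, and a generic over-representation test
   against GMT collections.
7. **Immunofluorescence statistics** — pooled counts per group and Fisher
   comparisons of marker-positive proportions.

The real cohort behind this design is not yet publicly deposited, so the
package ships a synthetic-data generator that reproduces the *statistical
structure* of the study, together with a ground-truth channel used by the
test suite to measure recovery.

## The synthetic cohort

`simulation_config()` describes 15 donors varying in binary amyloid and tau
pathology (8 and 7 positive by default) and in *APOE* (E3/E3 : E3/E4 :
E4/E4 = 0.60 : 0.27 : 0.13) and *TREM2* (WT : R47H = 0.8 : 0.2) genotypes,
and four nucleus populations in the study's proportions at one fifth of its
size: 1431 protoplasmic, 837 fibrous, 432 astrocyte–neuron doublets, 406
astrocyte–oligodendrocyte doublets, over 2000 genes.

**Latent reactivity.** Each protoplasmic nucleus carries `r` in [0, 1]:
Beta(2, 2) mass plus a donor random intercept (sd 0.05) plus an
`amyloid_shift` of 0.118 in amyloid-positive donors, clamped to the unit
interval. The shift value is the amyloid coefficient scale the pathology
model is expected to recover. Fibrous nuclei carry no trajectory.

**Gene programs.** 52 genes rise with `r` (log-scale slope +0.3) and 144
fall (slope −0.5); these are the "top programs" the screen must recover,
and they are modeled as well-expressed (log-baseline Normal(1, 0.5))
because threshold-passing genes in real tissue are. A further 600 genes
form a broad sub-threshold program with slopes Normal(0, 0.2): real
reactivity shifts a continuum of genes of which only the top pass
thresholds, and without this continuum the trajectory would carry far less
variance than the data the analysis is designed for — with only 196
informative genes among 2000, the leading signal eigenvalue sits inside the
Marchenko–Pastur noise bulk and *no* method could order the nuclei. Marker
panels (10 genes per population, log-boost 2.5 in their own population) are
labeled with familiar symbols (*SLC1A2*, *GFAP*, *RBFOX3*, *PLP1*, ...)
purely as labels. The two astrocyte subtypes express each other's panels at
a reduced boost (1.7): protoplasmic and fibrous astrocytes are one cell
type differing in degree, which keeps them adjacent in expression space
rather than disconnected islands. A `MALAT1` stand-in with log-baseline 4
reproduces the very high nuclear expressor excluded from MA plots.

**Counts.** Gene counts are negative binomial with per-gene dispersion
drawn log-normal(log 0.1, 0.4) around 0.1 — within a homogeneous population
UMI counts are near-Poisson, and the latent trajectory itself supplies the
biological variation — at an expected depth of 12,000 counts per nucleus.
The 2000 simulated genes stand for the expressed transcriptome, so the
*total* depth of a real nucleus is preserved rather than the per-gene
depth. Doublets are sums of two freshly simulated parent profiles
(protoplasmic + neuron or oligodendrocyte), thinned binomially back to the
singlet depth because a droplet yields one library's depth.

**What the generator does not emulate.** Ambient RNA, batch and chemistry
effects, UMI collisions, cell-cycle structure, and any spatial signal.
Passing recovery tests on this generator shows the pipeline correctly
inverts its own generative assumptions at realistic noise levels — not that
those assumptions exhaust real tissue.

## Design choices in the pipeline

**Denoising.** The original workflow denoises expression with an iterative
deep-learning model before clustering and regression. We substitute a
deterministic PCA/kNN smoother (`knn_smooth`): each nucleus becomes the
mean of itself and its `k = 30` nearest neighbors. Two choices matter:

- *Cluster-aware application.* Smoothing is applied within each analysis
  population (the astrocyte subset for the diffusion map, the protoplasmic
  subset for the screen), never across the whole dataset. Cross-population
  smoothing leaks expression over cluster boundaries and, through
  library-size normalization, imprints a compositional gradient on every
  gene that the screen then mistakes for trajectory association.
- *Dimensionality.* The smoother for the screen searches neighbors in 10
  PCs; the smoother feeding the diffusion map uses the map's own 30. With
  few, high-variance components the neighborhoods are tighter along the
  trajectory, so less per-gene signal is averaged away — the deciding
  factor for borderline effect sizes near the `|beta| > 0.1` threshold.

Clustering and Wilcoxon markers run on unsmoothed normalized data;
smoothing correlates nuclei and would distort rank-sum inference.

**Root rule.** The published analysis roots pseudotime at the minimum of a
force-directed layout axis where homeostatic expression is highest. Force
direction is layout-heuristic; we use the first nontrivial diffusion
component, sign-fixed so that the end with high homeostatic-panel
expression is negative, and take the axis minimum among protoplasmic
nuclei, breaking ties by homeostatic score and then lexicographic ID. This
is deterministic and testably places the root in the bottom decile of true
reactivity on synthetic data.

**Graph connectivity.** Pseudotime is computed on protoplasmic and fibrous
nuclei jointly. If the joint kNN graph is disconnected, `diffusion_map()`
errors by default; `compute_pseudotime()` instead bridges each minor
component to the largest through its nearest inter-component pair, with a
kernel bandwidth floored at the bridge distance so the weight cannot
underflow. Distances across such a bridge are near-constant, which is why
fibrous nuclei — with no planted trajectory — show near-degenerate
pseudotime spread (variance ratio well under 0.25 versus protoplasmic).
A side effect of one dominant between-population diffusion mode is that the
*raw* pseudotime of protoplasmic nuclei is compressed into a narrow band;
their ordering (all that the rank-based screen consumes) is unaffected. For
the pathology model, `pipeline_config(lmm_scale = "rank")` optionally
rank-uniformizes pseudotime before fitting; the default is the raw scale.

**Rank uniformization.** Pseudotime values are non-uniformly distributed,
and OLS against a skewed covariate is leveraged by its tails. Mapping to
`(rank − 1)/(n − 1)` gives an evenly spaced covariate, makes the screen
invariant to any strictly monotone distortion of pseudotime, and fixes the
scale on which the `beta_min = 0.1` threshold is interpreted. Raw integer
ranks are available (`rank_scale = "raw"`) but change beta's scale.

**Thresholds.** `beta_min` is applied two-sided: the screen reports both an
up and a (larger) down program, so the published "beta > 0.1" is read as a
magnitude. Bonferroni `m` is the number of genes actually tested after QC,
not a fixed constant. The slope p-value comes from the t distribution with
`n − 2` degrees of freedom.

**Mixed model.** Estimation delegates to `lme4::lmer` (REML); the module's
contribution is the design coding — E3/E3 and WT reference levels, 0/1
pathology, a random intercept per donor — and Wald p-values. Genotype
levels absent from a cohort are dropped rather than raising a singularity
error; genuinely collinear covariates still error, naming the column. Sex
is omitted: the cohort design is all-male. A constant response returns a
zero fit rather than an estimation failure.

**Exact tests.** The two-sided Fisher p sums the probabilities of all
tables with the observed margins that are no more probable than the
observed one (the common convention; the original's software is not
specified beyond a statistics GUI). Odds ratios are sample cross-product
ratios `ad/bc` and are reported, not tested against printed values, because
the published ORs are not exactly reproducible from the published counts.
The chi-squared statistic is the closed-form Pearson formula with an
optional Yates correction (off by default). The rank-sum test enumerates
all splits exactly when the smaller group has at most 6 members and uses
the tie-corrected normal approximation otherwise.

## Calibration of the screen and its null

The screen's null calibration (no planted slopes anywhere) is scored
against the rank-uniformized *planted* reactivity covariate, which under
the null is independent of expression by construction. This is the
statistically correct null for the regression-plus-thresholds rule; it also
avoids re-estimating a diffusion map on structureless data, where
"pseudotime" is an arbitrary functional of the noise and its smoothness
with respect to the same graph that smoothed the expression would inflate
the apparent false-positive rate of a test the screen is not running.
Under the null the screen classifies zero genes in nearly every run;
Bonferroni plus the effect-size and variance thresholds are jointly far
stricter than the nominal level.

The recovery scoring is sign-aware: a classified gene counts as a false
discovery only if its true slope is zero or of the opposite sign.
Sensitivity is measured on the 52/144 top programs; broad-program genes
called with the correct sign are true, if sub-threshold, associations.

The pathology-model recovery fits the generator's latent reactivity
directly (via `draw_reactivity()`): the 0.118 amyloid shift is planted on
the reactivity scale, and only a response on that scale can recover that
number. Fitting inferred pseudotime tests the same machinery but on a
scale set by the diffusion geometry.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the package's desk scale:
2000 genes; 2000 protoplasmic nuclei (five seeds) for pseudotime recovery;
3000 for screen recovery; 1000-nucleus cohorts for twenty null-calibration
runs; 50 cohorts of 15 donors x 100 nuclei for the mixed model; and the
full four-population default (3106 nuclei) for the end-to-end pipeline
test. Diffusion maps use dense symmetric eigendecomposition (exact and
deterministic at these sizes), kNN search is exact and block-wise, PCA is
unscaled and centered, and eigenvector signs are fixed by the
largest-magnitude entry. Ties in root selection are broken by homeostatic
score, then ID. Degenerate inputs are handled explicitly: zero-total nuclei
are a named error in normalization, constant genes get `beta = 0, p = 1`,
zero-variance ranked pseudotime is an error, and `k = 0` smoothing is the
identity.

## Known limitations

- The marker-panel annotation rule (mean log-fold-change of significant
  panel genes, doublet panels taking precedence) is an algorithmic proxy
  for the original's manual, literature-guided labeling.
- The kNN smoother is a linear, local denoiser; it cannot match an
  iterative model-based denoiser on real data, and it correlates nuclei, so
  downstream per-nucleus tests on smoothed data are anti-conservative. The
  screen's effect-size and variance thresholds, not its p-values, do the
  real gatekeeping.
- With a single dominant between-population mode, raw joint pseudotime
  compresses within-population scale (see above); rank-based analyses are
  unaffected, but raw-scale coefficients of the pathology model on joint
  pseudotime are attenuated relative to per-population analyses.
- Printed odds ratios and the exact background universes of the
  mouse-model comparisons are not reproducible from the published counts;
  the overlap machinery therefore exposes the universe as an explicit
  argument and treats ORs as descriptive.
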