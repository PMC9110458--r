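---
title: "Three-way decomposition and weighted co-expression analysis of multi-factor transcriptomes"
author: "triomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-way decomposition and weighted co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

# The analysis problem

An RNA-seq experiment over two crossed factors — here a panel of
genotypes sampled at several culm developmental stages (internodes), with
replicates — poses two linked questions.  First, *how is expression
variation structured*: how much of it is a developmental main effect
shared by all genotypes, how much is a stable genotype effect, and how
much is genotype-by-stage interaction?  Second, *which groups of
co-expressed genes track the agronomic traits* (sugar content, fibre
content) measured on the same genotypes, and which individual genes are
the strongest trait-specific candidates?

`triomics` answers the first question with a Tucker3 (three-way PCA)
decomposition of the genotype × gene × internode expression tensor, and
the second with a weighted co-expression network built from scratch:
soft-threshold selection by scale-free fit, unsigned adjacency,
topological overlap, module detection, module eigengenes, and
module/gene–trait statistics, followed by a trait-specific candidate
filtration.  A synthetic-data generator with fully known ground truth
ties the two streams together and is what the package's tests and
acceptance checks run on.

# The Tucker3 model

The replicate-mean expression values are arranged in an array
$X \in \mathbb{R}^{I \times J \times K}$ (genotypes × genes ×
internodes) and decomposed as

$$x_{ijk} = \sum_{p=1}^{P}\sum_{q=1}^{Q}\sum_{r=1}^{R}
  a_{ip}\, b_{jq}\, c_{kr}\, g_{pqr} + e_{ijk},$$

with orthonormal component matrices $A$ (genotypes), $B$ (genes), $C$
(internodes) and a core array $G$ whose element $g_{pqr}$ weighs the
association of component triple $(p, q, r)$.  With orthonormal loadings
the fitted sum of squares equals $\sum g_{pqr}^2$, so each squared core
element is directly that triple's share of explained variation — the
quantity `core_contributions()` tabulates.

**Centering.** Each gene is centred to grand mean zero across all
$I \times K$ cells, and *not* scaled, so highly expressed genes carry
more weight.  Replicates are averaged before centering.  Per-internode
centering is available (`center = "internode"`) but non-default.

**Fitting.** `tucker3()` uses orthonormal-loading alternating least
squares (TUCKALS3): each sweep replaces one mode's loadings by the
leading left singular vectors of the matricised tensor projected on the
other two modes, which cannot decrease the fitted SS; hence the residual
trace is non-increasing, a property the tests assert on every run.  The
fit is initialised with the higher-order SVD (per-mode singular vectors
of the unfoldings); optional random-orthonormal restarts guard against
local optima in hard cases.  Convergence is declared when the relative
change of fitted SS drops below `tol` (default `1e-8`, capped at 500
sweeps; non-convergence is flagged, not an error).  Unfolding column
order is fixed (mode 1: column $(k-1)J + j$, and analogously), and after
convergence each loading column is flipped so its largest-magnitude
entry is positive (compensated in the core), making cores reproducible
run to run.

**Model size.** `tucker3_grid()` fits every $(P, Q, R)$ combination up
to per-mode maxima (defaults 5, 20, 3 — a 300-model grid) and records
explained variance.  `choose_model()` automates the scree-plot
inspection this grid traditionally receives: candidate models are
ordered by total component count $S = P + Q + R$, the Pareto frontier
(best explained fraction per $S$) is formed, and the chosen $S$ is the
smallest beyond which *every* remaining per-step gain is below `eps`
(default 0.01).  Looking at all later gains rather than only the next
one matters: explained-variance curves over $S$ routinely plateau (a
dominant $g_{111}$ makes the $(1,1,1)$ model strong, while adding one
component to a single mode gains almost nothing) and then jump once
components in several modes combine, so a "first small gain" rule would
stop far too early.

**Main-effect attribution.** A mode component is *constant* when the
coefficient of variation of its loadings (sign-fixed so the mean is
positive) is below `cv_threshold` (default 0.2).  A core element whose
genotype component is constant describes variation among internodes only
(an internode main effect); one whose internode component is constant is
a genotype main effect; everything else is interaction.
`partition_main_effects()` sums fitted-SS shares per class.  A caveat
shown clearly by the synthetic design: when other genotype-structured
variation (for instance module activity) is present, a *fitted* leading
genotype component is a mixture and its CV can straddle the threshold;
the classification is sharp only when the underlying components are
cleanly constant, which is why the acceptance checks validate the
partition on constructions with an exactly constant component.

# Pre-processing conventions

* **Prevalence filter**: a gene is kept when it has at least
  `min_count` (10) reads in at least `min_fraction` (70%) of samples —
  the boundary is inclusive.  The zero-fraction filter used before
  network construction removes genes with *more than* 80% zeros — that
  boundary is strict.  Both match the verbatim reading of the
  conventions they implement, and both are idempotent.
* **TMM**: `tmm_factors()` implements the Robinson–Oshlack trimmed mean
  of M-values — reference library chosen by upper-quartile proximity to
  the mean, M and A values computed on library-size-normalised counts,
  two-sided trims of 30% (M) and 5% (A), precision weights — normalised
  to geometric mean 1.  `effective = TRUE` returns *effective* size
  factors, library size × composition factor (geomean 1), which fold
  depth and composition into one number: on two libraries that differ
  only by doubled depth the composition factors are (1, 1) while the
  effective factors are $(2^{-1/2}, 2^{1/2})$.
* **Normalisation**: counts go to $\log_2(\mathrm{CPM} + 1)$ with the
  effective library size ($N_k \times f_k$) in the denominator when TMM
  factors are supplied; TPM input goes to $\log_2(\mathrm{TPM} + 1)$
  with no further between-sample scaling.
* **Exploratory structure**: sample PCA on gene-centred data;
  hierarchical clustering of sample or genotype×stage mean profiles
  with Euclidean distance and classical `ward.D` linkage.  Where a
  $-\log_{10}$-style display transform appears in this literature, the
  magnitude transform $\log_{10}(x+1)$ is used for distances, since a
  global sign flip leaves Euclidean distances unchanged.  Trait tables
  are auto-scaled (per-trait z-scores) before display alongside
  dendrograms.

# The co-expression network

The network stream follows the weighted gene co-expression analysis
recipe with every step implemented in the package:

1. **Soft threshold.** For each candidate power the unsigned adjacency
   $a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$ is formed (diagonal 0) and
   the connectivity distribution is tested for scale-free shape:
   connectivities are binned into 10 equal-width bins and
   $\log_{10}$(bin frequency) is regressed on $\log_{10}$(mean bin
   connectivity).  The fit $R^2$ is signed by the slope (scale-free
   topology requires a negative slope).  The chosen $\beta$ is the
   smallest candidate reaching `target_r2` (default 0.80), else the
   argmax; the package default power is 4.  If all connectivities
   coincide (e.g. perfectly correlated genes) the fit is reported as
   degenerate rather than a number.
2. **Topological overlap.**
   $\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
   a_{ij})$ with $\ell_{ij} = \sum_u a_{iu} a_{uj}$; diagonal reported
   as 1.  Tests compare it entry-wise with a triple-loop evaluation of
   the definition.
3. **Module detection.** Genes are clustered on $1 - \mathrm{TOM}$ with
   `ward.D` linkage.  Modules are selected as branches of the tree in a
   single deterministic top-down walk.  A branch qualifies when it
   (i) holds at least `min_module_size` genes (default 500, matching
   large-transcriptome practice; the synthetic checks scale it down with
   their gene count), (ii) is *cohesive* — mean intra-branch TOM at
   least `min_cohesion` (default 0.05) — and (iii) is *separated* — the
   merge that absorbs it sits at least `separation_ratio` (default 2)
   times higher than its own internal root.  A qualifying branch whose
   two sides are far less connected across than within (cross-side TOM
   below $1/\texttt{separation\_ratio}$ of the tighter side's cohesion)
   is treated as a merger of distinct modules and its sides are searched
   recursively, but it is only dissolved if at least one side yields a
   module of its own; otherwise the most inclusive qualifying branch
   wins.  The rationale: a single cut height provably cannot both keep
   tight modules whole and leave an incoherent background unassigned
   (any height that maximises branch counts rewards splitting, and any
   pure size rule must accept background slices), so the package uses
   this branch-selection procedure — a static, simplified analogue of
   dynamic tree cut — instead.  The defaults come from the geometry of
   Ward trees: a module should be at least twice as tight as its
   separation, and the mean TOM of mutually independent genes sits an
   order of magnitude below 0.05 at these network sizes while genuine
   modules sit an order above.  Genes in no qualifying branch are
   labelled `grey`.  Module colours are assigned from a fixed palette in
   decreasing size order; they are reproducible labels, not claims about
   any other analysis' colours.
4. **Eigengenes and trait statistics.** A module eigengene is the first
   principal component of the module's gene-standardised expression,
   unit-norm, sign-fixed to correlate non-negatively with the module
   mean.  Module–trait and gene–trait associations are Pearson
   correlations with two-sided p-values from the exact t transform
   $t = r\sqrt{(n-2)/(1-r^2)}$, floored at `1e-300` so p stays in
   (0, 1].  Module significance is the plain mean of absolute gene
   significance over the module's genes, with the grey pool reported but
   flagged.

# Candidate-gene filtration

`top_k_by_significance()` ranks genes by $|r|$ to the trait (default
k = 100; ties broken lexicographically by gene id for reproducibility),
independently of module membership.  `trait_specific_candidates()` then
intersects that list with the module associated with the trait of
interest and removes genes that also belong to the module of an
antagonistic trait — the restrictive list of trait-specific co-expressed
candidates.  `positive_subset()` provides the "positively and
significantly correlated genes of a module" counts; "significant" means
unadjusted p < 0.05 by default (a Benjamini–Hochberg option exists),
since such counts are conventionally reported without multiplicity
correction.  Absolute gene significance is the default ranking; a signed
option is provided.

# The synthetic-data generator

`sim_config()` defaults describe the emulated study: 24 genotypes × 5
internodes × 3 replicates (360 libraries), 2,000 genes, planted Tucker3
ranks (2, 3, 2), and two antagonistic 200-gene modules with target
intra-module correlation 0.9 and trait loadings +1/−1.

* **Tensor signal.** Loadings are orthonormalised Gaussian matrices; the
  core is Gaussian with $g_{111}$ boosted to `main_effect_share` (0.55)
  of core SS — a dominant-main-effect regime.  By default the leading
  genotype component is the constant direction $1/\sqrt{I}$
  (`internode_main_effect = TRUE`), so the dominant element describes
  development shared by all genotypes.  The truth is then rotated to the
  all-orthogonal (HOSVD) form of the core before being recorded: random
  orthonormal loadings are only identified up to within-subspace
  rotation, so *core-element shares are only recoverable quantities in
  that canonical form* — this is what makes the planted-share
  recovery checks well-posed.  The signal is scaled to RMS `signal_sd`
  (1.0 on the log2 scale — typical two-fold effects) and Gaussian cell
  noise of SD `noise_sd` (0.1) is added.  The noise distribution of
  expression on the log scale is an assumption of the generator, not a
  claim about any dataset.
* **Counts.** Per-library log2 mean = per-gene baseline (uniform on
  log2-CPM 3–10) + the tensor value of the library's (genotype,
  internode) cell + the module effect.  Module activity is
  $z_{sm} = \sqrt{f}\,u_{g(s)m} + \sqrt{1-f}\,e_{sm}$ with
  `module_genotype_var` $f = 0.5$: half the activity variance is a
  stable genotype effect.  This genotype component is what makes a
  genotype-level phenotype attributable to module expression at all —
  with purely per-sample activity, the link between a per-genotype trait
  and per-sample expression is bounded near the chance level that any
  genotype-structured background gene attains.  A gene in a module with
  target correlation $\rho$ receives
  `module_effect_sd` $\times(\sqrt{\rho}\, z_{sm} + \sqrt{1-\rho}\,
  \varepsilon_{gs})$.  Counts are negative binomial with mean
  $2^{\log_2 \mu} \times \mathrm{libsize}/10^6$ and size
  `nb_dispersion` (10; `Inf` switches to Poisson), library sizes uniform
  on 5–15 million reads.
* **Traits.** Trait value = loading-weighted sum of standardised module
  activity + Gaussian noise (SD 0.2).  At the default genotype level the
  stable genotype component $u$ is used and one noisy value per genotype
  is replicated across its samples, matching per-genotype phenotyping;
  `level = "sample"` uses $z$ directly.
* **Determinism.** One root seed; each operation draws from its own
  derived sub-stream, so any stage can be reproduced independently and
  identical configurations are byte-identical.

**What the generator does and does not emulate.**  It reproduces the
design shape, count overdispersion, library-size variation, a planted
multilinear structure, co-expression modules and module-linked traits.
It does not emulate transcript-level effects, polyploid allele dosage,
batch effects, GC or length bias, outlier samples, or the long-tailed
mean–variance relationships of real libraries — so passing tests
demonstrate correctness of the algorithms under a faithful null model,
not performance guarantees on any particular real dataset.

# Problem sizes and numerical choices

The test-suite and acceptance runs use the full 360-library design with
2,000 genes (planted modules of 200, minimum module size scaled to 50
accordingly), smaller tensors (e.g. 10 × 200 × 5) for exactness checks,
and 20-seed batteries for the end-to-end recovery properties; these
sizes keep every check well within desk-scale compute while leaving the
statistical properties intact.  Other numerical conventions collected in
one place: ALS tolerance `1e-8` on relative fitted SS; loading-sign fix
by largest-magnitude entry; adjacency diagonal 0 but TOM diagonal 1;
p-value floor `1e-300`; trait auto-scaling uses the sample SD; all
tie-breaks (gene lists, model selection, module labels) are
lexicographic or size-ordered and therefore deterministic.

# Known limitations

* Tucker2/PARAFAC variants, missing-data fitting and loading confidence
  intervals are out of scope.
* The network stream holds the dense gene × gene matrices in memory;
  it is intended for desk-scale gene counts (up to a few tens of
  thousands), not block-wise decomposition of larger transcriptomes.
* Signed or signed-hybrid networks and robust (bicor) correlation are
  not provided; Pearson correlation is used throughout and missing
  values are an error, never silently dropped.
* The module detection procedure is a deliberate simplification of
  dynamic tree cut; on real data with nested module structure the
  `separation_ratio` and `min_cohesion` defaults may need inspection
  against the dendrogram.
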