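---
title: "Projecting community-weighted mean trait change in wetland vegetation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting community-weighted mean trait change in wetland vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitshift)
```

## The question and the model chain

Wetland ecosystem processes — carbon accumulation, nutrient retention, water
flow attenuation — are governed to first order by the traits of the species
that dominate community biomass (the mass-ratio hypothesis). A climate
scenario therefore translates into ecosystem consequences through a chain:
species' habitat suitabilities shift, their relative biomass shares shift, and
with them the community-weighted mean trait (CWMT),

$$\mathrm{CWMT}(x) \;=\; \sum_{s \in \text{pool}} \pi_s(x)\, t_s ,$$

where $\pi_s(x)$ is the relative biomass share of species $s$ in grid cell
$x$ and $t_s$ its trait value. `traitshift` implements this chain end to end:

1. **Presence-background SDMs per abundance class.** Occurrence records carry
   a three-level field abundance class (1 = single individuals, 2 = frequent,
   3 = dominant). Each (species, class) subset is fitted with a
   maximum-entropy model and projected onto current and scenario climates.
2. **Weighted-average relative abundance.** The three class probabilities are
   combined with weights $w = (0.01, 0.1, 1)$ — a dominant-class occurrence
   is worth a hundred single-individual occurrences — giving an occurrence
   value that tracks field abundance more closely than a plain presence
   probability.
3. **Allometric biomass weighting.** Canopy height $H$ (m) is converted to
   maximum potential biomass density via the power law
   $B_{\max} = 1.769\times10^{5}\,(H/b)^{-0.757/a}$ (kg DW m⁻²), with
   $a = 0.264$, $b = 2.58$ for non-trees and $a = 0.345$, $b = 3.71$ for
   trees. Shares are then
   $\pi_s(x) \propto A_s(x)\, B_{\max}(H_s)$, normalized per cell.
4. **CWMT and categorical profiles, per layer.** Continuous traits (specific
   leaf area SLA, canopy height CH, root depth RD) give CWMT surfaces;
   categorical traits (leaf persistence, clonality, mycorrhiza, and for
   hydrophytes body flexibility and space occupancy) give biomass-proportion
   profiles. Pools are evaluated per vegetation layer: the field layer pools
   pteridophytes, graminoids and herbs; shrubs form their own layer; trees
   are summarized separately; mosses are excluded (no trait or size data).
5. **Regionalization.** Per-cell species share changes are clustered with
   k-means (default $K = 5$) into regions of similar community change, and
   CWMT changes are averaged within regions.
6. **Species contributions.** Each species' leverage on a CWMT change surface
   is the standardized mean squared error incurred by leaving it out.

A synthetic-data module generates landscapes, species, occurrences, traits
and phylogenies with the statistical structure these stages assume, so the
full chain is testable — with known ground truth — without any external
rasters.

## The maximum-entropy SDM

For features $f(x)$ (standardized over the background) the model is the Gibbs
distribution $p_\lambda(x) \propto e^{\lambda \cdot f(x)}$ over background
cells that maximizes the L1-penalized log-likelihood

$$L(\lambda) = \overline{\lambda \cdot f}_{\text{presence}}
  - \log \sum_{x \in \text{bg}} e^{\lambda \cdot f(x)}
  - \beta \lVert \lambda \rVert_1 .$$

Design choices, all deliberate simplifications relative to the full Maxent
feature system:

* **Features**: linear and quadratic terms per continuous layer and one
  indicator per categorical code — sufficient for unimodal (Gaussian) niche
  responses; no hinge, product or threshold features. A Gaussian response
  $\exp(-(x-\mu)^2/2\sigma^2)$ is exactly representable, with the quadratic
  weight negative and implied optimum $-\lambda_{\text{lin}}/2\lambda_{\text{quad}}$.
* **Regularization**: a single global $\beta$ (default 0.1 per standardized
  feature) rather than Maxent's per-feature-class tuned defaults.
* **Background**: all valid cells; presences are also background cells (the
  standard presence-background convention). At desk scale (grids well below
  $10^5$ cells) no background subsampling is needed.
* **Optimizer**: proximal Newton — the log-partition term's gradient and
  Fisher-information Hessian define a quadratic model, solved under the L1
  penalty by cyclic coordinate descent, with backtracking on the true
  objective. The objective is concave, so the optimum is global; convergence
  is declared on the generalized gradient (default `tol = 1e-8`), and unit
  tests verify agreement with brute-force optimization of the same objective
  to better than $10^{-3}$ per coefficient.
* **Output scales**: `raw` (the Gibbs distribution, summing to 1 over the
  projection background) is the default used by the pipeline, since only
  relative magnitudes survive the subsequent share normalization. A
  `logistic` transform $1 - \exp(-e^{r} p_{\text{raw}}(x) N_{\text{bg}})$
  with $r$ the mean linear predictor over training presences is provided as
  a bounded, monotone display scale.
* **Sparse classes**: a (species, class) combination with fewer than
  `min_presences = 5` records is not fitted; the class weight is dropped from
  the weighted average's normalizer so the estimate remains a weighted mean
  of the classes actually modeled.

## The weighted average and the allometric law

Whether the class-probability combination is divided by $\sum w$ is
immaterial downstream — relative biomass shares are invariant to any global
factor — so both conventions are offered (`normalized`, the default, and
`sum`).

The biomass law is implemented exactly as printed, which makes $B_{\max}$
*decrease* with height ($-0.757/0.264 < 0$) and pins $B_{\max}(H{=}b)$ at the
prefactor $1.769\times10^{5}$. Combining the two underlying scaling laws
($H \propto M^{a}$, $N \propto M^{-0.757}$) as $B = M \cdot N$ would instead
give the exponent $(1-0.757)/a$, increasing in height. Because the derivation
lives in supplementary material we could not consult, the package implements
the printed form as the default and offers the derived exponent as
`mode = "derived"` for sensitivity analysis; CWMT *changes* are qualitatively
robust to the choice because it only reweights species consistently across
both scenarios.

## Phylogenetic gap filling

Continuous trait gaps are filled under univariate Brownian motion: with
phylogenetic covariance $C$ (shared root-to-MRCA path lengths), the ML
estimates are the GLS closed forms
$\hat\mu = (\mathbf{1}^\top C^{-1}x)/(\mathbf{1}^\top C^{-1}\mathbf{1})$ and
$\hat\sigma^2 = (x-\hat\mu)^\top C^{-1} (x-\hat\mu)/n$, and missing tips get
the conditional expectation
$E[x_m \mid x_o] = \hat\mu + C_{mo} C_{oo}^{-1}(x_o - \hat\mu)$ with its
conditional variance reported. Choices:

* traits are imputed independently (no multivariate trait covariance);
* SLA, CH and RD are fitted on the log scale and back-transformed — size
  traits are right-skewed and must stay positive (CH feeds a power law);
* ML rather than REML — the $O(1/n)$ bias is immaterial for imputation;
* categorical traits are never imputed: unknown levels are excluded from
  profiles and the excluded share count is reported.

## Regionalization and the contribution statistic

K-means uses k-means++ seeding, `n_init = 10` restarts, Lloyd iterations with
an in-loop monotonicity assertion, and an explicit empty-cluster rule
(reassign the point farthest from the largest cluster's centroid). Rows are
raw share changes — all columns are proportions, so no standardization is
applied — and labels are renumbered by descending region size with
centroid-lexicographic tie-breaks, making the labeling deterministic given
the seed. Unit tests check exact agreement with exhaustive enumeration on
six-point instances and with an independent implementation on separable data.

"Standardized" in the leave-one-out contribution score is taken as
standardization by the spatial variance of the full change surface:
$\text{score}_s = \overline{(\Delta_{-s} - \Delta)^2} / \operatorname{Var}(\Delta)$,
a scale-free convention comparable across traits. Zero-share species score
exactly 0 (their removal is a no-op), as do species whose trait everywhere
equals the community mean.

Regional averages weight cells equally (not by wetland area), and cells
masked in any input are masked in every derived surface for that pool.

## What the synthetic generator emulates — and what it does not

* **Landscapes**: continuous layers are Gaussian random fields (white noise
  low-pass filtered with a separable Gaussian kernel of sd
  `correlation_length` cells), standardized per layer; categorical layers
  are quantile cuts of auxiliary smooth fields, giving contiguous patches.
  Standardization fixes the marginal variance at 1 by construction; the
  variance-shrinking effect of heavier smoothing is exposed via
  `standardize = FALSE`. Layer units are therefore sd units, and scenario
  deltas are expressed on that scale.
* **Species**: Gaussian niche responses over a random subset of
  `niche_dims = 2` continuous layers with code preferences on one
  categorical layer. Low-dimensional niches mirror the empirical fact that a
  few predictors dominate most species' distributions, and keep synthetic
  species widespread enough to be recorded — the analysis targets common,
  potentially dominant wetland plants, not rarities.
* **Occurrences**: sites sampled without replacement; detection probability
  equals normalized abundance (presence-only semantics: high abundance is
  seen more often), and the recorded class thresholds normalized abundance
  at (0.1, 0.5]. These thresholds are a declared stand-in for the field
  protocol's class semantics, not a claim about it.
* **Traits**: Brownian motion on a random coalescent tree, exponentiated for
  size traits; categorical traits assigned deterministically per functional
  group so profile tests have known truth.
* **Not emulated**: dispersal limitation, species interactions, land-use
  change, observation bias correlated with accessibility, and real geography.
  Passing tests demonstrate that the estimation chain recovers the structure
  it assumes; they say nothing about these unmodeled processes.

## Numerical conventions

* Grids are R matrices addressed by 1-based `(row, col)`; row 1 is the top of
  the map; the ESRI ASCII origin is the lower-left corner. Grids are written
  at full double precision so round-trips are exact.
* A constructed-sign experiment ties trait values to thermal optima (high-SLA
  species prefer warmth), applies a warming offset that stays inside the
  niche-covered range of the landscape, and checks that CWMT SLA rises on
  essentially all community cells. That experiment uses $\beta = 0.3$:
  with occurrence records split three ways by abundance class, the middle
  class occupies an annulus in environmental space whose fitted curvature is
  noisy, and moderate shrinkage keeps per-class curvature estimates
  comparable across species. The default pipeline $\beta$ remains 0.1.
* Problem sizes used by the tests and the acceptance script — 32 × 32 grids,
  up to 24 species, 100 recovery replicates, 500 Brownian-motion replicates —
  were chosen to exercise every stage at well-conditioned sample sizes while
  keeping a full run in the tens of seconds.

## Known limitations

* The re-implemented maxent uses only linear/quadratic/indicator features;
  strongly skewed or multimodal responses would need hinge features.
* The printed allometric prefactor is physically enormous
  ($1.769\times10^{5}$ kg DW m⁻² at $H = b$); only relative biomass is used,
  so the prefactor cancels, but absolute biomass should not be read off
  `b_max()`.
* Imputation assumes Brownian motion; traits under strong selection or with
  measurement error will get over-confident conditional variances.
* The abundance-class weighted average is a heuristic bridge from occurrence
  probability to relative abundance, inherited deliberately from the study
  design it reproduces; it is a basis for comparison between scenarios, not
  a calibrated abundance model.
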