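---
title: "Methods: climate suitability and municipal economic risk for forest pest invasions"
author: "pestRisk package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate suitability and municipal economic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestRisk)
```

# What the package models

`pestRisk` estimates, for a plantation forest pest not yet present in a
region, (i) where the climate would suit it, (ii) where climatic
suitability coincides with a high likelihood of introduction, and
(iii) which municipalities carry the largest economic exposure through
their dependence on the host crop. The pipeline has four stages:

1. **Occurrence preparation** — spatial thinning of presence records to a
   minimum inter-record distance, and delimitation of the model-training
   background as the union of the climate zones that contain records.
2. **Predictor preparation** — cropping the predictor stack to the
   background and removing collinear variables by iterative VIF filtering.
3. **Suitability modelling** — a minimal MaxEnt: an L1-regularised Gibbs
   distribution over background cells, tuned over a regularisation-by-
   feature-class grid by AICc, and evaluated with AUC, a randomised
   null-model significance test and the Continuous Boyce Index.
4. **Risk synthesis** — multiplication with a normalised
   introduction-likelihood surface, Jenks natural-breaks classification,
   municipality-level zonal statistics, and a two-dimensional risk matrix
   combining suitability classes with the normalized Concentration Index
   (nCI) of the host crop's economic importance.

Every input can be produced by the synthetic-world module, so the entire
pipeline runs and is tested without any external download.

# The MaxEnt core

## Model

MaxEnt models the probability that a presence falls in background cell
$x$ as a Gibbs distribution over the background cells $B$:

$$p_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)},
  \qquad Z(\lambda) = \sum_{b \in B} e^{\lambda \cdot f(b)},$$

where $f(x)$ is a vector of *features* derived from the climate
predictors. With $m$ presence records the fit maximises the penalised
log-likelihood

$$J(\lambda) = \sum_{\text{presences}} \lambda \cdot f(x)
  \;-\; m \ln Z(\lambda) \;-\; \sum_j \beta_j |\lambda_j|.$$

Feature classes follow the conventional tokens: **L** (scaled identity),
**Q** (scaled square), **P** (scaled pairwise products) and **H**
(forward and reverse hinge ramps at quantile knots; 20 knots per variable
per direction by default). All features are scaled to $[0, 1]$ with the
background minima/maxima, so the L1 penalties are comparable across
features; values outside the background range are clamped. Presence rows
are appended to the background for $Z$ (the standard MaxEnt convention;
`addPresences = FALSE` disables it for analytic work).

Penalties follow the Phillips-style defaults:
$\beta_j = r \cdot \beta_{\text{class}}(m) \cdot s_j / \sqrt{m}$, with
$r$ the regularisation multiplier, $s_j$ the background standard
deviation of feature $j$, and $\beta_{\text{class}}$ interpolating from
1.0 (at $m \le 10$) through 0.2 (30) to 0.05 ($m \ge 100$) for
linear/quadratic/product features and fixed at 0.5 for hinges.

## Optimisation

The objective is concave but, with hinge expansions, extremely
ill-conditioned: dozens of near-collinear ramp features create long flat
ridges on which first-order (proximal-gradient) updates crawl —
improvements decay like $1/k$ and the iterate is still drifting after
thousands of steps. The package therefore uses a **proximal Newton**
scheme (`src/maxent_fit.cpp`): each outer iteration builds the local
quadratic model of the log-likelihood from the gradient and the Gibbs
covariance of the features, solves the L1-penalised quadratic subproblem
by cyclic coordinate descent with soft-thresholding (with a glmnet-style
active set between full sweeps), and safeguards the step with a halving
line search on the exact objective. The recorded objective is therefore
monotone non-decreasing by construction; iteration stops when an accepted
step improves the objective by less than `tol` ($10^{-7}$ by default) or
at `maxIter` (5000) iterations, in which case the best iterate is
returned with a warning. On the desk-scale worlds used in the tests all
50 tuning candidates converge, most in a handful of outer iterations and
the heaviest hinge-product candidates in the low hundreds.

## Outputs

`predictSuitability()` returns the raw Gibbs density (summing to 1 over
the training background; used internally for AICc) or the cloglog map
transform $1 - \exp(-e^{H}\,\text{raw})$ with $H$ the entropy of the
fitted background distribution — the modern MaxEnt default for maps. The
two outputs rank cells identically.

# Tuning and evaluation

`tuneModels()` crosses ten regularisation multipliers (0.5–5 in steps of
0.5) with five feature-class sets (L, Q, LQ, LQH, LQHP): 50 candidates.
Each candidate is fitted once on the full occurrence set and scored by
AICc, $2k - 2\ln L + 2k(k+1)/(n-k-1)$, with $k$ the number of nonzero
weights, $n$ the occurrence count, and $\ln L$ computed from raw scores
renormalised over the prediction grid. AICc is undefined (NA) when
$k = 0$ or $k \ge n - 1$. Ties are broken by smaller $k$, then smaller
multiplier. AUC (Mann–Whitney with ties counted half) and the Boyce
index are reported for a single random 75/25 train/test split of the
occurrences scored against the background — the split method is a design
choice; refitting per partition would multiply the grid cost without
changing the selection, which depends only on AICc.

The **null-model test** refits the selected settings on `nNull`
replicates of equally many occurrences drawn uniformly from the
background area and records the same test-split AUC as the empirical
model. Significance requires the empirical AUC to *strictly* exceed at
least $\lceil 0.95\,n_{\text{null}}\rceil$ of the null AUCs — ties count
against significance, the conservative reading of the 95% exceedance
rule. On no-niche species (presences drawn uniformly) the empirical
type-I rate sits at its nominal few percent (checked by Monte Carlo in
the acceptance suite at a scaled-down 20×20 / 30-presence / 50-null
configuration, 40 repeats).

The **Continuous Boyce Index** uses 101 overlapping windows of width 10%
of the landscape score range (common ecospat-style settings; both are
arguments). Windows with zero expected mass are dropped; fewer than
three usable windows yields NA. Because the windows live on the raw
score scale, the index is only *approximately* invariant under strictly
increasing score transforms; the test suite asserts stability within
0.1 under cubing for a well-behaved monotone construction. An exactly
rank-based variant (windows on the quantile scale) was considered and
rejected to stay close to the field-standard definition.

# Jenks classification and risk synthesis

`jenksBreaks()` is the exact Fisher–Jenks dynamic program (O($kn^2$),
implemented in C++) minimising total within-class sum of squared
deviations; a brute-force partition enumeration verifies it exhaustively
in the tests. For large rasters breaks are computed on a uniform random
sample of at most 10,000 cells (seed recorded) — the DP cost, not
statistical precision, motivates the cap. Boundary rule throughout:
intervals are right-closed, so a value equal to a break falls in the
lower class.

The invasion-risk surface is the cellwise product of the suitability map
and the min–max-normalised introduction surface (bilinear resampling if
grids disagree). Suitability maps are classified into four classes
(unsuitable / marginally / moderately / highly suitable); plantation
polygons are rasterised at a five-fold finer resolution (the 30
arc-second vs 2.5 arc-minute ratio) with the cell-centre rule, and the
per-class area fractions are reported. The same cell-centre rule drives
the municipality zonal means, keeping polygon↔raster membership
consistent across operations.

# The economic risk matrix

For product $i$ and municipality $j$, with $VP_{ij}$ the municipal value
of the product, $VP_j$ the municipal total forestry value and national
totals $VP_{i\cdot}, VP_{\cdot}$:

$$LQ_{ij} = \frac{VP_{ij}/VP_j}{VP_{i\cdot}/VP_{\cdot}}, \qquad
  HHI_{ij} = \frac{VP_{ij}}{VP_{i\cdot}} - \frac{VP_j}{VP_{\cdot}}, \qquad
  RP_{ij} = \frac{VP_{ij}}{VP_{i\cdot}},$$

and $nCI_{ij} = \theta_1 LQ_{ij} + \theta_2 RP_{ij} + \theta_3 HHI_{ij}$.
$RP$ sums to 1 and $HHI$ to 0 across municipalities by construction, and
all indices are invariant to the currency unit. The weights $\theta$
come from a PCA on the correlation matrix of the three index columns:
each index's weight is the explained-variance-share-weighted sum of its
absolute loadings (normalised within each component), renormalised to
sum to 1 — the Crocco-style construction; absolute loadings remove the
eigenvector sign ambiguity, and the index columns are z-standardised
both for the PCA and for the weighted sum. Both conventions are
arguments (`standardize`), because the index literature states the PCA
weighting at varying levels of detail; the implemented formula is the
package's documented interpretation.

Mean municipal suitability and nCI are each classified into five Jenks
classes (1 = lowest); the risk score is the arithmetic mean of the two
class indices and maps to four levels with right-closed boundaries:
very low $(0, 1.5]$, low $(1.5, 2]$, moderate $(2, 3]$, high $(3, 5]$.
Municipalities with zero product value are retained (their nCI is
simply minimal), so the classification covers every producing
municipality.

# Occurrence thinning

Thinning enforces a minimum great-circle distance (haversine, Earth
radius 6371 km; 20 km by default) between retained records while keeping
as many records as possible. Exact duplicates are removed first. The
maximum-retention problem is a maximum independent set on the conflict
graph: for up to 25 records the package solves it *exactly* by branch
and bound, which makes the optimality postcondition checkable against
exhaustive search; larger sets use the replicated randomised
max-conflict-removal heuristic familiar from spThin (remove a record
with the most close neighbours, random tie-break, keep the best of
`nReplicates` runs), whose replicate retention counts are reported in
the thinning report rather than asserted.

# The synthetic world

The generator emulates the structure of the real inputs with known
ground truth:

* **Climate stack** — each band is white noise smoothed with a Gaussian
  kernel (correlation length `smoothness` cells, default 10) and
  standardised; designed collinear pairs are mixed as
  $\rho\,b_i + \sqrt{1-\rho^2}\,b_j$ and re-standardised, landing the
  realised correlation within ±0.05 of the target on worlds that are
  large relative to the correlation length. Defaults mirror the real
  study grids: 2.5 arc-minute cells and 15 bands (14 bioclim-style
  variables plus elevation).
* **Virtual species** — a product-Gaussian niche response with known
  optimum and tolerance; presences are sampled at cell centres with
  probability proportional to the surface, so thinning distances and
  recovery targets are exact.
* **Zones** — k-means on standardised predictor vectors, playing the
  role of a Köppen–Geiger zonation for background delimitation.
* **Production table** — a designed number of municipalities jointly
  holding a designed share of national product value; totals are
  conserved exactly.
* **Ancillary layers** — an arbitrary-ranged smooth introduction
  surface (so normalisation is actually exercised), a cell-aligned
  rectangular municipality tiling with exactly known cell membership,
  and rectangular plantation patches.

What the synthetic world does *not* emulate: sampling bias in occurrence
records, non-Gaussian niche shapes, categorical predictors, realistic
geography or climate-change projections. Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions,
not predictive skill on real species.

## Problem sizes used by the tests

Unit tests run on a 30×30-cell world with 5 predictors and 50–60
presences. The acceptance suite uses the sizes its checks are defined
at: 40×40 cells / 60 presences / 1000 background points for the
50-candidate tuning grid; 100×100 cells / 200 presences / 5000
background points for virtual-species recovery (Spearman ≥ 0.9 against
the true surface); and a deliberately scaled-down 20×20 / 30-presence /
50-null configuration, 40 Monte-Carlo repeats, for the null-model
type-I-rate check. Acceptance worlds use 6 predictor bands — enough for
a designed collinear pair plus independent axes while keeping the LQHP
feature expansion (267 features) desk-sized.

# Numerical choices and degenerate inputs

* VIF is computed on at most 10,000 sampled background cells (seed
  recorded in the report); removal ties break by band order. Perfect
  collinearity reports VIF = ∞ rather than erroring.
* Constant rasters normalise to all zeros with a warning; constant
  features evaluate to 0 and can never enter the model; constant index
  columns are an error naming the index.
* Features constant on the background get zero gradient and stay out of
  the model without special-casing.
* Municipality polygons with no cell centre yield NA with a warning
  rather than silently dropping out.
* All stochastic steps (sampling, k-means, splits, null draws) take
  explicit seeds and are bit-reproducible.

# Known limitations

* The MaxEnt implementation covers L/Q/H/P features; threshold and
  categorical features, clamping diagnostics and the jackknife of the
  Java reference are out of scope, and `permutationImportance()` is an
  AUC-drop analogue of the reference permutation importance, not a
  parity implementation.
* Grids are lightweight in-memory matrices with plain-text I/O (ESRI
  ASCII, CSV, GeoJSON); there is no tiling for rasters that do not fit
  in memory and no reprojection — all layers must share a geographic
  CRS.
* Area fractions are cell-count fractions in degree space, not
  equal-area km²; polygon features are single rings (no holes,
  no multipolygons).
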