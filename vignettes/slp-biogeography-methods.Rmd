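---
title: "Methods: phylogenetic biogeography of style-length polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic biogeography of style-length polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, the parameters that matter, the numerical choices, and what the
synthetic benchmark does and does not establish about real data.

## The scientific question and the data model

Style-length polymorphisms (SLP) — heterostyly and related floral morph
systems — are binary at the genus level here: a genus is polymorphic if at
least one species exhibits SLP. The analysis asks whether SLP occurrence
across all angiosperm genera is associated with tropical distribution,
biodiversity-hotspot occupancy, or genus species richness, once the
phylogenetic relatedness of genera is accounted for.

A dataset (`slp_dataset`) couples four aligned pieces: a rooted,
time-calibrated genus-level phylogeny; the 0/1 trait vector; a design
matrix with `tropical` (0/1), `hotspot` (0/1) and `species_richness`
(count) columns; and provenance counts for every genus dropped during
alignment (absent from the tree, missing distribution, missing richness —
dropped, never imputed, because no defensible imputation exists at this
scale). Tips, trait entries and design rows are kept in identical order by
construction, and the family include/exclude subsets re-prune the tree
while preserving that invariant.

## Biogeographic coding

A region is *tropical* when its latitudinal extent intersects the closed
band ±23.45° (23°27′, the astronomical tropics — the conservative core
shared by the common alternative definitions of "tropical"). A genus is
coded 1 when at least a threshold fraction of its occupied regions carries
the flag; the tie at exactly the threshold resolves to 1, following the
"at least" reading. The threshold defaults to 0.50 with 0.70 as the
conservative alternative; the alternative threshold applies to the
tropical coding only, because tropicality is gradient-based whereas
hotspot membership is categorical. Hotspot flags are input data
(precomputed overlap with the recognized hotspots), not computed from
polygons.

Genus centroids are area centroids of the 2-D convex hull of the occupied
regions' centroids, computed on raw (lon, lat) coordinates. Degenerate
cases are defined, not rejected: one point is its own centroid, two points
give their midpoint, and collinear points give the midpoint of the two
extreme points (the same limit the area formula approaches). Ranges
spanning more than 180° of longitude are not re-wrapped across the
antimeridian; they are flagged on the result instead. Centroids of
multi-continent genera can therefore fall in an ocean — an accepted
property of this centroid definition, not an error. Spatial weights use
great-circle (haversine) distances on a 6371-km sphere by default; planar
degrees are available mainly for closed-form test oracles.

## Exploratory stage

The non-phylogenetic first pass uses Pearson χ² on the 2×2 tables of trait
versus each geographic coding, a Welch t-test comparing species richness
between trait states, and collinearity diagnostics (variance inflation
factors from the 1/(1−R²) construction; pairwise φ for binary predictor
pairs, with significance via χ² = nφ²). Yates' continuity correction is on
by default for 2×2 tables — the common statistical-environment default —
and is a single argument to disable; both conventions are exercised in the
tests. All p-values are two-sided. The t-test runs on raw species counts
by default (a log10 option exists), matching the count scale on which the
regression coefficient for richness is reported.

## Phylogenetic signal: the D statistic

For a binary trait, ancestral node values are estimated in postorder as
unweighted arithmetic means of the immediate children (polytomies need no
special handling — the mean runs over all children; branch lengths play no
role in this sum), and `d_obs` is the sum over edges of |child − parent|.
The statistic scales `d_obs` between the means of two simulated nulls:
uniform permutations of the trait across tips (phylogenetic randomness),
and Brownian motion of a liability along the branch lengths from a root
value of 0, thresholded so that exactly the observed number of state-1
tips receive state 1 (highest liabilities win; liability ties break by tip
index). D ≈ 1 under randomness and D ≈ 0 under threshold-Brownian
conservatism are the calibration contract of the estimator, and the
acceptance suite verifies both ends empirically (200 replicates on 200-tip
pure-birth trees at prevalence 0.1, 100 simulations per null within each
replicate — sizes chosen to make the Monte-Carlo error of the replicate
mean a small fraction of the ±0.15 calibration band).

`p_random` is the fraction of random-null sums ≤ `d_obs` (small values
reject randomness); `p_brownian` the fraction of Brownian-null sums ≥
`d_obs` (small values reject conservatism). The default 1000 simulations
per null put the resolution of these p-values at 0.001. The RNG seed is
recorded in the result.

Branch lengths enter only through the Brownian simulation; the node-mean
sum itself is topological. This reproduces the published calibration
targets, which are the statistic's contract; the exact internal variant
used by other implementations is not published to that level of detail.

## Phylogenetic logistic regression

The model is the field-standard mean-reversion formulation:
`E[y_i] = logit⁻¹(x_i'β)` with between-tip dependence decaying with
patristic distance as `exp(−α d_ij)`; large α means no phylogenetic
correlation. Because the exact joint likelihood of correlated Bernoulli
tips is intractable, the package fits by maximum *composite* likelihood
with a tree-structured (Chow–Liu style) objective:

* marginal Bernoulli terms for every tip, plus
* pairwise interaction terms `log P_ij − log p_i p_j` along the minimum
  spanning tree of the patristic distance matrix — each tip interacts with
  its nearest phylogenetic neighbours, n−1 pairs in total;
* an edge pair's joint success probability is
  `P11 = μiμj + exp(−α d_ij) √(μi(1−μi) μj(1−μj))`, truncated strictly
  inside its Fréchet bounds `[max(0, μi+μj−1), min(μi, μj)]` so all four
  cell probabilities stay positive.

This construction was chosen over the two tempting alternatives after both
failed structurally. A Gaussian working likelihood on Pearson residuals
(with or without REML-style projection and scale profiling) can be gamed on
sparse traits: driving fitted probabilities toward a boundary makes the
residual vector nearly constant or nearly a few spikes, which mimics
perfect correlation and inflates the criterion without bound. A pairwise
composite likelihood over *all* n(n−1)/2 pairs cannot be balanced against
the n marginal terms: normalized per observation it is too weak to detect
real signal; unnormalized it dominates the marginals and explodes. The
spanning-tree objective has neither defect: it is a genuine approximate
joint log-probability, bounded above by 0 because every pair probability
is bounded by its margins, so no parameter configuration can manufacture
unbounded correlation evidence; and its interaction terms vanish
identically at α → ∞, so the fit reduces *exactly* to ordinary logistic
regression in the no-signal limit (the star-tree equivalence asserted to
1e-3 relative error in the acceptance suite holds to ~1e-7 in practice).

β is maximized (BFGS, relative tolerance 1e-12, warm-started along the
profile) at each candidate α; α is profiled on a log scale over a 12-point
grid spanning `[1e-4/T, 1e4/T]` (T = tree height — the bounds bracket
correlation ranges from effectively 1 to effectively 0 at typical
distances), refined by golden-section search around the best grid point.
An α estimate at either bound is reported via `alpha_at_bound`. Standard
errors come from the numerical Hessian of the objective at the optimum; as
with all composite-likelihood information matrices they are approximate,
and the simulation tests therefore assert sign recovery and calibration of
the point estimates rather than coverage.

Firth's penalty (half the log-determinant of the logistic information
matrix, which is α-free) is applied by default: with trait prevalence
around 2%, quasi-separation is a practical certainty in subsets.
`fit_logistic()` — the phylogeny-free reduced model — uses plain maximum
likelihood with an automatic, flagged Firth fallback under separation.
Equivalence checks against the non-phylogenetic limits compare like with
like: unpenalized phylogenetic fits against `glm`-style maximum
likelihood, penalized fits against Firth logistic regression.

### Partial R² and model comparison

`R²lik = 1 − exp(−(2/n)(ℓ_full − ℓ_reduced))` attributes explanatory power
to one component by full-versus-reduced comparison: each covariate's
reduced model refits without that covariate; the phylogeny's reduced model
is ordinary logistic regression with identical covariates — the α → ∞
limit of the same objective, so the comparison is nested by construction.
The accompanying p-value is a χ² likelihood-ratio test with df = 1 per
removed component (for the phylogeny component, the single parameter α);
a bootstrap alternative was considered and rejected as disproportionate to
the desk-scale problem sizes. All fits in one decomposition use the same
penalization mode. Exact nesting holds for the unpenalized objective; the
Firth penalty term differs between designs of different width, so under
penalization a reduced fit can in principle edge out the full fit by a
fraction of a unit — `partial_r2_table()` guards against the related
profiling artifact by re-offering every winning reduced solution
(dropped coefficient at zero) to the full model's profile, and clamps a
residual negative difference to R² = 0 with a warning.

AIC = 2k − 2ℓ with k counting regression coefficients plus α; Akaike
weights are normalized `exp(−ΔAIC/2)`. The three fixed configurations
(all predictors; without hotspot; without tropical) follow from the
moderate correlation between the two geographic codings: rather than
choosing one coding, the analysis reports all three fits and lets ΔAIC < 2
and the weights identify the defensible set.

### Phylogenetic linear regression

`fit_phylolm()` is generalized least squares with Brownian covariance
σ²C, C the shared root-to-tip path lengths, σ² its maximum-likelihood
estimate, used for the richness ~ hotspot question on the family-excluded
data. It is exact (Cholesky + QR, no iteration) and collapses to ordinary
least squares on a star tree with equal branch lengths.

## Spatial autocorrelation

Phylogenetic eigenvectors are the leading eigenvectors of the
double-centered (Gower/PCoA) transform of −½ D∘D, D the patristic
distance matrix; the PCoA-style centering (rather than eigenvectors of the
raw distance matrix) is the package's documented choice because it is the
construction under which ultrametric distances embed with nonnegative
eigenvalues. k = 10 eigenvectors by default, selected by descending
eigenvalue, configurable. The trait is residualized by ordinary least
squares on an intercept plus the eigenvectors — OLS residuals of a 0/1
trait are the conventional input to Moran's I, and logistic Pearson
residuals are available as an option since the original choice is
ambiguous in this setting. Rank-deficient bases drop dependent columns
with a warning rather than failing.

Moran's I uses inverse great-circle distances with a zero diagonal;
coincident centroids of distinct genera (which would give infinite weight)
receive the maximum finite weight in the matrix, preserving
"closest = heaviest" without infinities, and their count is recorded. The
null moments use the closed-form normality variance (`E[I] = −1/(n−1)`
exactly); the randomization (kurtosis-corrected) variance differs by a few
per mille on Gaussian-like residuals, which the cross-check against an
independent implementation makes visible and the tests tolerate
explicitly.

## The synthetic benchmark: what it emulates, and what it does not

The generator reproduces the *structural* features the analysis must cope
with: an ultrametric genus-level tree (pure-birth by default, 500 tips at
benchmark scale); 368 regions with about half touching the tropical band
and hotspot flags enriched within it; phylogenetically structured
occupancy — each genus occupies `1 + Poisson(mean−1)` regions nearest a
Brownian-evolving home latitude, so related genera share geography and
phylogeny is confounded with space exactly as the analysis fears;
lognormal species richness (log-mean 1.8, log-sd 1.5 — median a handful
of species, occasional thousand-species genera); and a trait from a
Brownian threshold liability with prevalence around 2% under the default
intercept. The liability takes the richness effect per order of magnitude
(log10), because with a raw-count effect the lognormal tail alone decides
which genera cross the threshold, and the trait degenerates into "the
largest genera" instead of a phylogenetically structured character. The
`logistic` trait mode (independent Bernoulli draws given the covariates)
exists because the liability scale is unidentified, as in every threshold
model: liability-mode recovery tests assert sign and ordering only, while
logistic-mode data calibrate `fit_phyloglm` exactly.

What passing tests on this benchmark do *not* show: robustness to
taxonomic name mismatches, non-random missingness, biased regional
checklists, antimeridian-spanning ranges, or trait misclassification —
none of which the generator emulates. Real-data conclusions inherit those
caveats from the inputs.

Every generator is deterministic under its seed; the components derive
distinct sub-seeds (seed, seed+1, ...) so that tree, geography, richness
and trait draws are independent streams.

## Problem sizes and numerical conventions

The test and acceptance runs use: 200 replicates × 200 tips for D
calibration; 100 replicates × 300 tips for effect-sign recovery; 500
genera for the end-to-end study (about 10 s); 1000 simulations per null
for reported D statistics and 100–200 within replicated calibration loops.
These sizes were chosen so each check's Monte-Carlo error is small against
the property it asserts while the whole suite stays interactive.

Ties and degenerate inputs are defined once and tested: threshold ties
code to 1; liability ties break by tip index; constant traits, empty
occupancy, zero marginals, zero-variance groups and all-zero weight
matrices raise errors with explicit messages; exactly collinear predictors
report infinite VIF with a warning. Patristic-distance correlation
matrices get a 1e-8 diagonal regularization before Cholesky in the linear
GLS; fitted probabilities are clamped away from 0/1 at 1e-9 inside the
composite objective.

## Known limitations

* Composite-likelihood standard errors and the χ² reference for the
  likelihood-ratio p-values are approximations; the package's simulation
  evidence covers point-estimate behaviour, not interval coverage.
* The spanning-tree objective captures nearest-neighbour dependence; very
  diffuse signal spread over distant pairs contributes only through the
  profile of α, so the phylogeny partial R² is conservative relative to a
  full joint-likelihood treatment.
* Hull centroids on raw coordinates misplace antimeridian-spanning ranges
  (flagged, not corrected).
* The D statistic is reported for any trait with both states present, but
  with a handful of state-1 tips its sampling variance is large; the
  per-dataset values on sparse subsets should be read with their
  simulation p-values.
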