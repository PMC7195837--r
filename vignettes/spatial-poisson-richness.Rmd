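---
title: "Spatial hierarchical Poisson models for richness gradients with spdepois"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial hierarchical Poisson models for richness gradients with spdepois}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdepois)
```

## The model

`spdepois` estimates the effect of environmental gradients — atmospheric
nitrogen deposition above all — on plant species richness recorded in small
quadrats, while accounting for spatial autocorrelation at two scales. The
observation model is a hierarchical Poisson regression with a log link:

$$y_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
\lambda_{ij} = \exp\Big(\beta_0 + \sum_{m=1}^{M}\beta_m X_{mij}
 + \beta_j Q_{j[i]} + \omega_{ij}\Big)$$

where $y_{ij}$ is the richness count of plot $i$ in 1-km grid square $j$,
$\beta_j \sim N(0, \theta^2)$ is an iid intercept shared by plots of the
same square (fine-scale autocorrelation: several plots can fall in one
square), and $\omega$ is a zero-mean Matérn Gaussian Markov random field
capturing broad-scale spatial structure — unmeasured, spatially smooth
drivers such as historic land use or deposition mismeasurement. Dropping
terms gives the four error structures the package compares by DIC:
`mesh_plus_square`, `square_only`, `mesh_only`, `none`.

Richness counts sit at the plot scale; pollutant and climate covariates are
modelled surfaces at 5 × 5 km or coarser grain, which is one reason a
residual spatial field is scientifically plausible rather than a nuisance
afterthought.

### The SPDE representation of the Matérn field

The field is not given a dense covariance matrix. Instead it is represented
as the finite-element solution of the SPDE whose stationary solution has
Matérn covariance (smoothness $\nu = 1$ in 2-D, i.e. operator order
$\alpha = 2$). On a triangulated mesh with piecewise-linear basis functions,
the field weights $w$ at the mesh nodes get the sparse precision

$$Q = \tau^2\,(\kappa^4 C + 2\kappa^2 G + G C^{-1} G),$$

with $C$ the *lumped* (diagonal) mass matrix and $G$ the stiffness matrix.
Lumping keeps $C^{-1}$, and hence $Q$, sparse — the standard GMRF
implementation of the method. The practical range (correlation $\approx
0.13$) is $\rho = \sqrt{8}/\kappa$ and the marginal standard deviation
$\sigma = 1/\sqrt{4\pi\kappa^2\tau^2}$. The value of the field at a plot is
the barycentric interpolation of the three surrounding node weights
(`projector()`), which reproduces affine functions exactly.

The mesh (`build_mesh()`) triangulates the unique 1-km square centroids of
the data (national-grid convention: square origin `floor(coord/1000)`,
centroid at +500 m), surrounded by a convex ring pushed outward by a
fraction of the domain diameter so that the Neumann boundary of the FEM
solution — which inflates variance near the mesh edge — sits away from the
data. Mesh construction details are not scientific claims; they are exposed
(`boundary_extension_fraction`, `max_edge`, `max_edge_outer`) and the mesh
summary is printable precisely so that mesh sensitivity can be examined.
Defaults: extension 0.15 of the domain diameter; refinement limits 10 grid
squares interior / 40 in the ring when enabled. Delaunay triangulation is
done by incremental Bowyer–Watson insertion with a strict in-circle
predicate; grid centroids are exactly cocircular in quadruples, so the
predicate is evaluated under a tiny deterministic shear, which breaks every
tie the same way and keeps the node degrees (and therefore the lumped-mass
variance) regular. On a ~460-node test mesh the implied correlations match
the closed-form Matérn $\nu=1$ function within 5% over $[0.1\rho, \rho]$
and the marginal variance within a few percent (boundary excluded); this is
the level of fidelity at which the field should be read.

## Inference

The model is a latent Gaussian model: conditional on the hyperparameters
$\theta = (\log \mathrm{prec}_u, \log\tau, \log\kappa)$, the latent vector
$(w, u, \beta_0, \beta)$ has a Gaussian prior and a Poisson likelihood.
Full nested-Laplace machinery is deliberately *not* re-implemented; the
package's contract is the model and its summaries, with two independent
inference routes that must agree:

* **`laplace_eb`** (default): Newton optimization of the latent conditional
  posterior gives a Gaussian (Laplace) approximation at each $\theta$; the
  hyperparameter posterior $p(\theta \mid y)$ is approximated by the
  standard Laplace evidence and explored on a regular grid of mode ± 2.5
  posterior sds, 5 points per dimension (both configurable). Fixed-effect
  marginals are exact normal mixtures over the grid; mixture quantiles are
  found by root-finding on the mixture CDF, not by sampling.
* **`mcmc`**: a one-block Metropolis–Hastings sampler. Each iteration
  proposes $\theta'$ by a random walk scaled to the Laplace curvature and
  the *entire* latent field from its Gaussian approximation at $\theta'$,
  accepting jointly. The Gaussian proposal absorbs the strong
  $\theta$–field dependence; acceptance rates are typically 30–50% and the
  acceptance ratio corrects the approximation error exactly, so the sampler
  targets the exact posterior. Split-chain $\hat R$ for the fixed effects
  and the acceptance rate are reported, and `converged` is flagged rather
  than silently passed.

The test suite holds the two routes to agreement within 0.1 posterior sd
for the regression-coefficient medians on a 150-plot synthetic fit. The
intercept is the one quantity where the empirical-Bayes route is visibly
weaker (a systematic ~0.1 sd offset against the exact sampler on such
fits): with an improper intercept prior the intercept trades off against
the free level of the zero-mean spatial field, and the symmetric Gaussian
mixture misses the resulting skew. The covariate effects — the quantities
the analysis is about — are unaffected.

### Priors

"Package defaults" are version-dependent, so the defaults here are pinned
and recorded in every output: fixed effects $N(0, \mathrm{prec} = 0.001)$;
improper flat intercept; square-effect log-precision $\sim$ log-gamma(1,
5e-5); wide Gaussians (sd 1.5) on $(\log\tau, \log\kappa)$ centred so the
prior median range is 20% of the mesh domain diameter and the prior median
field sd is 1. With one plot per square everywhere, $\theta^2$ is weakly
identified and the fit flags when its posterior looks prior-dominated
(posterior curvature close to the prior's).

Covariates are **not** centred or standardized internally: the divisor
rescaling of the preparation step (below) is the only transformation, so a
coefficient for deposition reads "per kg ha$^{-1}$ yr$^{-1}$" and remains
comparable across studies. The intercept therefore anchors the covariate
origin, not the data centroid, which is also why partial-effect curves at
"other covariates zero" predict low absolute counts.

## Covariate preparation

`prepare_design()` reproduces a deliberately boring pipeline — boring is
the point, since covariate handling is where gradient studies diverge:

* **Divisor rescaling** (`rescale_covariate()`): altitude ÷ 100 ("per
  100 m"), precipitation ÷ 250, topsoil pH ÷ 0.5, and so on; the built-in
  `covariate_catalogue()` records the divisors and raw ranges for the two
  emulated surveys. Reported values are rounded to 2 decimals; internal
  computation keeps full precision.
* **Collinearity screening** (`correlation_screen()`) reports pairs above a
  threshold but never drops anything: the two deposition covariates are
  strongly collinear (r ≈ 0.83 in the clustered survey, r ≈ −0.70 in the
  scattered one) and are retained on purpose — collinearity inflates
  variance, it does not bias coefficients, and both pollutants are the
  scientific question. No stepwise or any other automated variable
  selection exists in this package.
* **Mean imputation** (`mean_impute()`) for the small block of plots with
  missing PET; the regression-based alternative is documented to make no
  substantive difference and is out of scope.
* **Climate PCA** (`climate_pca()`): four highly intercorrelated climate
  variables are replaced by their first two correlation-matrix principal
  components ("Climate PC1/PC2"). Columns are standardized first because
  the inputs mix units; each component's sign is fixed so its loading on
  the first input column is non-negative, making scores platform-stable.
* **VIFs** (`vif()`): classical least-squares auxiliary regressions,
  $\mathrm{VIF}_m = 1/(1-R^2_m)$. The original analysis computed VIFs
  "using Poisson GLMMs" without defining the formula; the classical VIF is
  the default here, and passing `group =` conditions the auxiliary
  regressions on square membership as a proxy for the mixed-model variant.
  The discrepancy is documented, not resolved.
* **Grazing intensity** (low/medium/high) enters as two treatment-coded
  indicators with "low" as reference — the original coding is unstated, and
  treatment coding against the lowest intensity is the natural choice.

One published rescaled endpoint is internally inconsistent (a lower
precipitation endpoint printed as 0.42 where the divisor gives 2.42); the
catalogue stores the self-consistent value.

## Diagnostics

* **DIC** (`dic()`): $\mathrm{DIC} = \hat D + 2 p_D$, $p_D = \bar D - \hat
  D$. $\bar D$ averages the deviance over joint posterior draws (grid cell
  sampled by weight, then latent vector from its Gaussian approximation);
  the plug-in $\hat D$ is evaluated at the **posterior mean of the linear
  predictor** $\eta$, the classical hierarchical-model convention that
  keeps $p_D \ge 0$ in practice (plug-ins at the mean of $\lambda$ behave
  worse; which convention the original software used is unstated, so the
  choice is pinned here). Negative $p_D$ is flagged, never hidden.
* **Variance partition** (`variance_partition()`): the share of
  random-effect variance captured by the structured field is computed as
  the empirical variance of the posterior-mean field at the plot locations
  against that of the posterior-mean square effects at the plots. How the
  published 87–99.7% figures were computed is not defined anywhere; this
  empirical-variance-of-posterior-means reading is one defensible choice
  and is stated in the output rather than pretending to be canonical.
* **Partial effects** (`partial_effect()`): the posterior of
  $\exp(\beta_0 + \beta_c x)$ along the decile grid
  (`percentile_grid()`, 0th–100th percentiles, linear-interpolation rule)
  of a covariate, all other covariates at zero, summarized from 4,000
  seeded joint draws of $(\beta_0, \beta_c)$ by default.

## The synthetic generator

No plot data ship with the package; `simulate_survey()` generates surveys
with the statistical structure the analysis assumes, so every stage is
testable offline and parameter recovery can be scored against known truth.
Two presets emulate the study designs:

* `"sea04"`: 68 sites × 5 plots (340; the `"archived"` variant keeps a
  320-plot subset, matching the publicly archived table), each site's plots
  inside one 100 × 100 m block; deposition pair correlated at 0.83; grazing
  factor; default $\exp(\beta_{\mathrm{ndep}}) = 0.99$.
* `"mea10"`: 883 scattered single plots with a fraction of squares holding
  several plots; deposition pair at −0.70; default
  $\exp(\beta_{\mathrm{ndep}}) = 1.01$.

Covariates come from a Gaussian copula with the target correlation matrix,
each column mapped affinely (rank-preserving) onto its published raw range —
the sources state ranges and correlations, not marginal shapes, so scaled
Gaussians are an assumption, and one that real soil variables (skewed,
plot-level) certainly violate. The spatial field is sampled from the same
SPDE GMRF the fitter uses (default synthetic magnitudes: range 150 km, sd
0.35, square sd 0.1 — the studies' own field parameters are not archived,
so these are plausible, clearly synthetic, choices that put most
random-effect variance in the structured field, as the published partitions
do). Default effect sizes bracket the published multiplicative range
{0.98–1.01}. What passing recovery tests therefore shows is that the
*inference machinery* is calibrated for data generated under the model's
own assumptions — not that real surveys satisfy those assumptions:
stratified land-class sampling, community matching of plots, surveyor
error and non-linear responses are all deliberately not emulated.

## Numerical choices and problem sizes

* Newton inner loop: step-halving line search, convergence at $10^{-8}$
  relative movement; linear predictors clamped at 30 on the log scale to
  prevent overflow from degenerate starts.
* Hyperparameter mode search: Brent (1-D) or Nelder–Mead (2–3-D) with a
  numeric Hessian for the grid scale; non-convergence flags the fit.
* Latent marginal sds are mixed over the grid for the (small) fixed-effect
  block exactly; field and square-effect sds use the modal grid cell plus
  between-cell dispersion — a documented economy, since extracting every
  per-cell marginal variance of a large field is cubic-ish work for a
  cosmetic refinement.
* All stochastic paths (sampling, draws, MCMC, simulation) take explicit
  seeds; default 20100429. Results are bit-reproducible given a seed.
* Test and validation problem sizes were chosen as the smallest that make
  the checks sharp: a ~460-node mesh for the Matérn-correlation oracle
  (dense inversion is exact there), 150–340-plot surveys for fit checks, 200
  replicates for recovery (the binomial band for a nominal 0.95 coverage at
  $n = 200$ is 0.92–0.98, and the Monte-Carlo noise floor of the bias-to-sd
  ratio, about 0.07, sits below the 0.1 criterion), 20 replicates for the
  DIC direction check.

## Known limitations

* Linear responses only: unimodal/threshold deposition responses are real
  possibilities and are out of scope here, as is measurement-error
  modelling of the 5 × 5 km pollutant surfaces.
* The Laplace route's hyperparameter posterior lives on a small grid;
  quantiles of hyperparameters (not of fixed effects) are correspondingly
  coarse.
* No WAIC/LOO (DIC only, for comparability); no non-stationary, barrier,
  anisotropic or spherical SPDE variants; no negative-binomial or
  zero-inflated responses; no shapefile/GeoTIFF I/O (mesh and field export
  as plain CSV keyed by coordinates).
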