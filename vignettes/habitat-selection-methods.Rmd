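---
title: "Methods: two-stage habitat-selection inference with habsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage habitat-selection inference with habsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(habsel)
```

habsel implements a two-stage inference chain for landscape-scale habitat
selection by a large carnivore: prey relative-abundance surfaces from
replicated detection/non-detection surveys (stage 1), feeding — together
with environmental and anthropogenic rasters — used–available resource
selection functions (RSFs) from telemetry, with demographic-class
interactions (stage 2). This vignette documents the models, the tunable
parameters, the synthetic-data generator used to verify the chain, the
numerical choices, and the limitations a user should know about.

## Stage 1: occupancy modelling of prey

### Observation models

Detection histories are binary vectors over *spatial* replicates:
consecutive road segments within a site (an 8 × 8 km grid cell
intersected with the surveyed road network). Three observation models are
available, all fitted by unconstrained quasi-Newton maximum likelihood on
link scales (log for abundance, logit for probabilities):

* **Constant detection** (`"mackenzie"`): site occupancy probability
  $\psi$, replicate detection probability $p$; the site likelihood is
  $\psi \prod_j p^{y_j}(1-p)^{1-y_j} + (1-\psi)\,[\text{all } y_j = 0]$.
* **Markov replicate dependence** (`"markov"`): within an occupied site,
  local presence $z_j$ along consecutive segments follows a two-state
  chain with colonisation $\theta_0 = P(z_j{=}1 \mid z_{j-1}{=}0)$,
  persistence $\theta_1 = P(z_j{=}1 \mid z_{j-1}{=}1)$ and initial
  probability $\pi_0$, with detection Bernoulli($p\,z_j$). The chain is
  marginalised with the forward algorithm. $\pi_0$ is estimated as a free
  parameter: published variants of this model differ in how the chain is
  initialised, and a free $\pi_0$ nests the stationary start.
* **Abundance-induced heterogeneity** (`"royle_nichols"`): local
  abundance $N_i \sim \text{Poisson}(\lambda_i)$ with $\log \lambda_i =
  x_i^\top a$, per-individual detection probability $r$, replicate
  detection probability $1-(1-r)^{N_i}$. The likelihood truncates the
  Poisson sum at an adaptive bound $K$: the smallest $K$ (floor 50) whose
  tail mass at the largest site $\lambda$ is below $10^{-8}$. A
  user-supplied $K$ that leaves more tail mass is refused rather than
  silently truncated. Because detection is exchangeable given $N$, the
  site likelihood depends on the history only through the detection count
  and the replicate count, which the implementation exploits for
  vectorisation. A logit-linear hook for a detection covariate on $r$
  (e.g. replicate count) exists but defaults off.

Numerics: multi-start optimisation (3 starts, the first at
method-of-moments-flavoured values, the rest jittered SD 0.5), BFGS with
a Nelder–Mead fallback, covariance from the inverse numerical Hessian,
and a large finite penalty ($10^{10}$) instead of infinite likelihoods so
the optimiser can retreat from impossible regions (e.g. $r = 0$ with a
detection). Degenerate designs are tolerated but flagged: with a single
replicate per site only the product $\psi p$ is identified.

### Replicate length

`selectReplicateLength()` implements the stepwise rule: starting at the
2-km base segment, the replicate length grows in 2-km multiples
(OR-merging consecutive base segments, trailing remainders discarded)
until the constant-detection model beats the Markov comparator by at
least 2 AICc. The returned trace records both AICc values at every
length tried; if the rule never fires the maximum length is returned
with a warning. AICc throughout is
$-2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ = sites.

### Covariate selection and averaging

`modelSelection()` chains: (1) univariate Royle–Nichols fits, keeping
covariates with Wald $p < 0.05$ on the abundance coefficient — the
univariate screen needed an explicit test and the Wald test on the
coefficient is the conventional choice; (2) a pairwise correlation filter
(|Pearson r| > 0.70 drops the higher-AICc member, worst pair first, ties
broken lexicographically for determinism); (3) all-subsets fits over the
survivors (≤ 10 candidates), AICc-ranked with Akaike weights
$w_m \propto e^{-\Delta_m/2}$; (4) conditional averaging over the
$\Delta \le 2$ support set, $\bar\beta_j = \sum_m w_m \beta_{jm} / \sum_m
w_m$ over models containing $j$. `predictAbundance()` exponentiates the
averaged linear predictor on a stack standardized with the fitting-time
record.

### Goodness of fit

`gofBootstrap()` computes Pearson $\chi^2$ over observed vs expected
detection-history frequencies, pooling sites into cohorts by replicate
count and adding the leftover expected mass of unobserved histories as a
single category. Expected frequencies are computed *exactly* (closed
forms for the constant and Markov models; the truncated Poisson sum for
Royle–Nichols) rather than by Monte Carlo: the per-history probability
depends only on the detection and replicate counts, so the exact sums are
both faster and noise-free. Bootstrap datasets are simulated from the
fitted model and refitted from the fitted parameters (single start);
$p$ is the fraction of bootstrap $\chi^{2*}$ at least as large as
observed and $\hat c = \chi^2_{obs} / \overline{\chi^{2*}}$. A refit
failure rate above 10% is an error, not a silently shrunken bootstrap.

## Stage 2: home ranges and resource selection

### Telemetry cleaning

`preprocessTelemetry()` applies, per individual: a greedy forward
impossible-movement filter (drop any fix implying a step speed above
`maxSpeed`, default 10 000 m/h — a deliberately permissive ceiling that
removes only GPS artefacts); daily subsampling keeping the fix nearest
local noon (a fixed, documented rule; the choice of which daily fix to
keep is otherwise arbitrary); and a residency rule that flags 14-day
windows whose net squared displacement exceeds 10 × the individual's
median and removes the fixes inside them. The 10× multiple deserves a
note: the windowed NSD of a *resident* animal with a Gaussian-kernel
range is approximately exponential, for which a 3× cut would flag ~12% of
perfectly residential windows and cascade into discarding most of a
stationary track; at 10× a resident exceeds the cut in well under 1% of
windows while a genuine range shift of several home-range diameters
exceeds it immediately. Only April–October fixes are retained, tagged
with the calendar year as the season id.

### Demographic classes

`assignClass()` is a pure function of birth date, sex and season start:
subadult iff age ≤ 4.0 years at the season start (the boundary is
inclusive, taking the "≤ 4 years" definition literally), crossed with
sex. Reference class for all reporting is the adult female.

### Utilization distributions and isopleths

`pluginBandwidth()` returns a diagonal 2 × 2 bandwidth matrix with
separate per-axis bandwidths from the univariate direct-plug-in selector
(KernSmooth's `dpik`) applied marginally — "separate bandwidths" per
axis, without the off-diagonal term; a normal-reference fallback
($H_{ii} = \sigma_i^2 n^{-1/3}$) is selectable. `kdeUD()` evaluates the
separable Gaussian KDE on the grid and renormalises cell masses to sum to
1; if more than 1% of the kernel mass falls off-grid it errors and asks
for a larger extent instead of silently renormalising a clipped surface.
`isopleth()` takes the density-ranked cell cut — the smallest cell set
reaching the level, which is optimal among all cell sets (verified
against exhaustive search in the tests) — polygonises the mask boundary
into closed rings, and reports the number of disjoint components as a
contiguity flag rather than forcing contiguity. Individual-seasons with
fewer than 60 distinct days (two months) of data are skipped.

### Used–available design and the mixed model

`buildDesign()` draws, per home range, `ratio` (default 4) available
points per used point, uniformly over the isopleth cells (all cells share
one area, so uniform cell choice plus uniform within-cell jitter is exact;
draws that leave the covariate raster are redrawn, making availability
uniform over isopleth ∩ raster). The 1:4 ratio is enforced *within* each
range-season, which also balances availability across groups. One shared
standardization record covers the whole design: the stack's own record
when its layers are already standardized (keeping coefficients on the
landscape z-scale), otherwise means/SDs over the design points.

`fitGlmm()` fits the logistic mixed model by Laplace-approximated ML
(lme4, `nAGQ = 1`), with covariate main effects, the class main effect,
the requested covariate × class interactions (treatment contrasts,
adult-female reference) and arbitrary lme4 random terms (nested
`individual/rangeSeason` by default). An empty random specification
reduces exactly to ordinary logistic regression. Singularity and
non-convergence are flags on the returned object, not errors.
`reduceReStructure()` starts maximal (random intercept + per-covariate
slopes with correlations) and simplifies: correlations dropped first
(on singularity or failure), then slopes whose variance falls below
$10^{-4}$ on the standardized scale or whose removal changes the
log-likelihood by less than half the 5% $\chi^2_1$ critical value,
with a random-intercept floor. The thresholds are our operationalisation
of the published parsimony procedure, which describes a balance rather
than a rule.

`lrtTermDeletion()` tests interactions first (each against the full
model, df = classes − 1 = 3), removes the non-significant ones jointly,
then tests main effects not under a retained interaction (df = 1). The
final model keeps all significant terms plus any main effect involved in
a retained interaction. `oddsRatios()` reports $e^\beta$ with
$e^{\beta \pm 1.96\,SE}$ (the 1.96 multiplier is fixed; no profile CIs).
`r2Nakagawa()` uses the latent-scale variance partition with logistic
link variance $\pi^2/3$, $\sigma^2_f$ = variance of the fixed linear
predictor over the design, $\sigma^2_r$ = summed random-effect
variances. `predictRsfMap()` exponentiates the class-specific linear
predictor and also returns a [0, 1] min–max rescaled copy for display;
both single-model and averaged-coefficient prediction paths are just
coefficient tables, so either can be mapped.

## The synthetic-data generator

The generator exists so every stage can be checked by parameter
recovery; it emulates the *statistical structure* the analysis assumes,
not any real geography.

* **Covariate fields** are Gaussian random fields — white noise smoothed
  by FFT convolution with a Gaussian kernel of the requested correlation
  range — plus an optional linear trend (SW→NE or NW→SE), min–max
  rescaled to each layer's value range (precipitation 400–680 mm rising
  to the northeast by default; NDVI and canopy noise-dominated). No
  spatial covariance model is prescribed by the study system, so field
  parameters are user-set; the defaults are chosen to look like a
  semi-arid mosaic, not calibrated to any study area.
* **Features**: uniform settlement points with Poisson household counts
  (density weights scaled by a mean household size of 3.7), uniform
  waterholes, and a meandering west–east river discretized to points
  100 m apart for the water layers.
* **Prey surveys**: a systematic road network (one west–east transect per
  site row, so every site holds one cell-width of road), site abundance
  $N \sim \text{Poisson}(\bar\lambda_{site})$, and detections that are
  either independent Bernoulli$(1-(1-r)^N)$ per segment (the
  Royle–Nichols regime) or driven by a segment-level Markov presence
  chain for exercising the replicate-length rule. In the test scenarios
  the "independent" survey uses $\theta_0 = \theta_1$ with $r$ near 1 —
  making detections literally independent within occupied sites, so the
  constant-detection model is exactly true — and the clustered survey
  uses $\theta_1 \gg \theta_0$.
* **Telemetry**: per class, fixes are drawn by exact rejection sampling
  from intensity $\propto e^{\beta_c^\top x(s)}\,k(s - c)$ with an
  isotropic Gaussian home-range kernel $k$ (closed-form isopleths for
  testing), proposals from $k$ itself and acceptance
  $e^{\beta^\top x(s) - \max}$ capped at the grid maximum — exact, no
  MCMC. Timestamps jitter around local noon across the Apr–Oct window;
  birth dates are drawn consistent with each class.

### What recovery runs can and cannot show

The end-to-end recovery study (telemetry → cleaning → UDs → design →
GLMM) uses a 60 × 60 km landscape of 500-m cells, covariate variation at
the cell scale (correlation range 1000 m, precipitation with a mild
SW→NE trend), home-range kernels of SD 6 km, 3 individuals per class
with daily fixes over one dry season, the normal-reference bandwidth,
and a random intercept per individual. These sizes keep the default test
suite and the acceptance script to a few minutes on one CPU.

Two structural facts shaped those choices, and users should know them
because they apply to real analyses too:

1. **Availability defined by use erases same-scale selection.** The 95%
   UD isopleth is estimated from the used points, so its centre and
   shape track selection. For a covariate that is locally linear across
   a home range (any smooth gradient), the availability domain recentres
   on the selected side and the within-range contrast vanishes — the
   used–available coefficient for such a covariate is attenuated toward
   zero regardless of sample size. Recovery is only possible for
   covariate variation at scales *below* the isopleth's smoothing scale,
   which is why the recovery landscape varies at the cell scale.
2. **Isopleths that chase patches attenuate patchy covariates.** With a
   small plug-in bandwidth the isopleth lobes follow the fixes into
   selected patches, dragging availability toward used habitat. The
   smoother normal-reference bandwidth keeps the home range contiguous
   and near-elliptical — also our reading of the published requirement
   that seasonal ranges be *contiguous*, which fragmented small-bandwidth
   isopleths violate — and preserves most of the selection contrast.

Passing recovery tests therefore shows the chain is internally coherent
under these conditions; it does not certify that coefficients from real
data are free of the attenuation above, which is a property of
third-order used–available designs generally, not of this
implementation.

The generator also deliberately omits: movement autocorrelation
(fixes are independent draws, no Ornstein–Uhlenbeck or hidden-Markov
movement), multi-season dynamics, non-Gaussian or multi-nuclear home
ranges, and any real road or river geometry.

## Interfaces and numerical conventions

Rasters are exchanged as ESRI ASCII grids (plain-text, georeferenced,
readable by QGIS/ArcGIS/GDAL; row 1 is the northern edge), vectors as
GeoJSON in projected metres, tables as CSV with ISO-8601 timestamps,
configuration and truth records as flat `key = value` text. All analysis
constants live in `runConfig()` exactly once: site grid 8000 m, base
replicate 2000 m, |r| 0.70, VIF 3, ΔAICc 2, isopleth 0.95, ratio 4,
α 0.05, 1000 bootstrap replicates, 10 000 m quartic kernel radius,
subadult boundary 4 y, 60-day minimum, Apr–Oct season. Every stochastic
function takes an explicit seed and restores the caller's RNG state;
rerunning a pipeline stage with the same configuration yields
byte-identical artifacts and manifests. Cell-value extraction is
containing-cell (no interpolation) on the projected grid; distances are
Euclidean with no geodesic correction, appropriate at study scale in a
projected CRS.

## Known limitations

* The Markov and constant-detection comparators share no code with an
  external occupancy package in this environment; they are validated
  against brute-force enumeration oracles instead (to $10^{-8}$ on toy
  sets) — see the test suite.
* VIF pruning and the correlation screen treat covariates as exchangeable
  columns; no hierarchy or grouping of predictors is honoured.
* The bootstrap GoF pools histories by replicate count; sparse cohorts
  with many unique histories give a coarse χ² (the unobserved-history
  mass is a single category).
* Home-range polygons are cell-boundary traces, not smoothed contours;
  their area is exactly the masked-cell area.
* The used–available estimand caveats above.
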