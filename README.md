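# habsel

Two-stage habitat-selection inference for large carnivores in
semi-arid, multi-use landscapes: **(1)** prey relative-abundance surfaces
from replicated track-survey detection histories fitted with occupancy
models that correct for imperfect detection, and **(2)** demographic-class
resource selection functions (RSFs) from GPS telemetry, contrasting used
locations with availability inside kernel home ranges.

The package is aimed at quantitative ecologists who have (a) road-transect
presence/absence surveys of prey species and (b) telemetry from a
collared predator population split into demographic classes (adult female,
subadult female, adult male, subadult male; subadult ≤ 4 years at the
start of the April–October dry season), and who want per-class
relative-selection maps over environmental and anthropogenic covariates.
A synthetic-landscape generator with recorded ground truth makes the whole
chain verifiable by parameter recovery.

## The models

**Stage 1 — prey occupancy.** Road transects are divided by an 8 × 8 km
grid into sites, and the road in each site into 2-km spatial replicates
scored for track presence. Detection heterogeneity is modelled through
latent local abundance (Royle–Nichols): with N<sub>i</sub> ∼
Poisson(λ<sub>i</sub>), log λ<sub>i</sub> = x<sub>i</sub>ᵀa and
per-individual detection probability r, a replicate at site i detects with
probability 1 − (1 − r)<sup>N<sub>i</sub></sup>. Spatial dependence between
consecutive replicates is diagnosed by comparing a constant-detection
model (MacKenzie) with a Markov-chain comparator (Hines): the replicate
length is doubled in 2-km steps until the MacKenzie model wins by ≥ 2
AICc. Covariates pass univariate screening (Wald p < 0.05), a pairwise
correlation filter (|r| > 0.70 drops the higher-AICc member), all-subsets
AICc ranking with Akaike weights, and conditional model averaging over
the ΔAICc ≤ 2 set. Fit is checked by Pearson χ² with parametric
bootstrap (ĉ = χ²<sub>obs</sub>/mean χ²*). The averaged coefficients give
λ(x) = exp(a₀ + āᵀx), a relative prey-abundance surface.

**Stage 2 — lion RSF.** Telemetry is cleaned (impossible-movement filter,
daily subsampling, residency rule), and each individual-season with ≥ 60
days of data gets a kernel utilization distribution (UD) with per-axis
direct-plug-in bandwidths and a 95% isopleth home range. Used fixes are
paired 1:4 with available points drawn uniformly inside the isopleth, and
a logistic mixed model (Laplace ML, lme4) with class interactions is fit:

logit P(used) = βᵀx + γ<sub>class</sub> + δ<sub>class</sub>ᵀx + b<sub>individual</sub>

with random structure reduced by a parsimony rule and fixed terms tested
by single-term-deletion likelihood ratio tests (interactions first,
df = 3). Reporting gives β, SE, Wald Z, OR = e<sup>β</sup> with 95% CI
e<sup>β±1.96·SE</sup>, LRT χ², AIC and marginal/conditional R²
(logistic link variance π²/3). Per-class maps are
w(x) = exp(βᵀx + γ + δᵀx).

## Worked example

Fit a Royle–Nichols model to a simulated survey (150 sites, 8 replicates
of 2 km, true slope 0.8 on NDVI, true r = 0.3):

```r
library(habsel)
set.seed(7)
x <- rnorm(150)
N <- rpois(150, exp(0.2 + 0.8 * x))
y <- matrix(rbinom(150 * 8, 1, rep(1 - (1 - 0.3)^N, 8)), 150, 8)
records <- data.frame(site = rep(sprintf("s%03d", 1:150), each = 8),
                      replicate = rep(1:8, 150),
                      detection = as.integer(t(y)))
dh <- buildDetectionHistories(records,
        data.frame(site = sprintf("s%03d", 1:150), ndvi = x))
fit <- fitOccupancy("royle_nichols", dh, covariates = "ndvi")
fit
#> OccupancyFit [royle_nichols]: 150 sites, logLik -615.171, AICc 1236.506
#>              estimate     se
#> lambda(Int)    0.2705 0.1237
#> lambda(ndvi)   0.7462 0.0843
#> r(logit)      -0.8378 0.1371
```

The abundance slope (0.75 ± 0.08) and detection probability
(plogis(−0.84) = 0.30) recover the simulation truth. The parametric
bootstrap confirms fit:

```r
gof <- gofBootstrap(fit, dh, nBoot = 200, seed = 1)
#> chi^2 = 230.9, bootstrap p = 0.77, c-hat = 0.91
```

(p is the fraction of bootstrap χ²* at least as large as observed — no
lack of fit; ĉ ≈ 1 means no overdispersion.) Odds-ratio reporting for an
RSF coefficient table:

```r
oddsRatios(c(0.42, -0.98), c(0.09, 0.12))
#>          or     lower     upper        formatted
#> 1 1.5219616 1.2758339 1.8155710 1.52 (1.28-1.82)
#> 2 0.3753111 0.2966507 0.4748293 0.38 (0.30-0.47)
```

A 1-SD increase in the first covariate multiplies the relative selection
odds by 1.52; the second (e.g. distance to water) strongly decreases
selection. The full synthetic pipeline — landscape, prey survey,
occupancy surface, home ranges, RSF, report tables and four per-class
maps — runs with:

```r
runStage("all", runConfig(seed = 1), outdir = "my_run")
```

or from the shell via `inst/scripts/habsel-cli.R`. See the methods
vignette (`vignettes/habitat-selection-methods.Rmd`) for the modelling
details and design choices.

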