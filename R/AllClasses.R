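#' @import methods
#' @importFrom stats AIC aggregate approx as.formula binomial coef complete.cases
#'   cor dist dnorm dpois glm lm logLik median na.omit optim optimHess pchisq
#'   pnorm ppois qchisq qlogis plogis quantile rbinom rnorm rpois runif sd
#'   setNames update var vcov fft anova simulate
#' @importFrom utils combn head read.csv tail write.csv
NULL

#' Regular raster grid geometry
#'
#' Describes a north-up regular grid in projected map units (metres): number
#' of rows and columns, lower-left corner of the extent, and square cell
#' size.  Row 1 of any associated value matrix is the northernmost row,
#' matching the usual raster convention.
#'
#' @slot nrow,ncol integer grid dimensions.
#' @slot xmin,ymin numeric coordinates (m) of the lower-left corner.
#' @slot cellsize numeric cell edge length (m).
#' @export
setClass("GridSpec",
  representation(nrow = "integer", ncol = "integer",
                 xmin = "numeric", ymin = "numeric", cellsize = "numeric"),
  validity = function(object) {
    if (object@nrow < 1L || object@ncol < 1L) return("grid dimensions must be positive")
    if (object@cellsize <= 0) return("cell size must be positive")
    TRUE
  })

#' Single-layer raster
#'
#' A numeric matrix of cell values tied to a [GridSpec-class] geometry.
#'
#' @slot values numeric matrix, \code{nrow(grid)} x \code{ncol(grid)}, row 1 north.
#' @slot grid the [GridSpec-class].
#' @export
setClass("RasterGrid",
  representation(values = "matrix", grid = "GridSpec"),
  validity = function(object) {
    g <- object@grid
    if (nrow(object@values) != g@nrow || ncol(object@values) != g@ncol)
      return("value matrix does not match grid dimensions")
    TRUE
  })

#' Aligned stack of named covariate layers
#'
#' Named covariate rasters sharing one grid, together with the
#' standardization record (per-layer mean and SD) needed to z-score new
#' data with the fitting-time scaling and to back-transform coefficients.
#'
#' @slot layers named list of numeric matrices, all of the grid's dimensions.
#' @slot grid shared [GridSpec-class].
#' @slot standardization data.frame with columns \code{layer}, \code{mean},
#'   \code{sd}; zero rows when no layer has been standardized.
#' @export
setClass("CovariateStack",
  representation(layers = "list", grid = "GridSpec", standardization = "data.frame"),
  validity = function(object) {
    g <- object@grid
    if (length(object@layers) &&
        (is.null(names(object@layers)) || any(!nzchar(names(object@layers)))))
      return("all layers must be named")
    for (nm in names(object@layers)) {
      m <- object@layers[[nm]]
      if (!is.matrix(m) || nrow(m) != g@nrow || ncol(m) != g@ncol)
        return(sprintf("layer '%s' does not match the grid", nm))
    }
    if (!all(c("layer", "mean", "sd") %in% names(object@standardization)))
      return("standardization record needs columns layer, mean, sd")
    TRUE
  })

#' Replicated detection histories for occupancy modelling
#'
#' Per-site binary detection records over ordered spatial replicates.  The
#' replicate count varies across sites (sites hold different lengths of
#' road), so histories are stored NA-padded in a matrix for vectorised
#' likelihood evaluation.
#'
#' @slot y integer matrix (sites x max replicates) of 0/1 detections,
#'   NA-padded on the right for sites with fewer replicates.
#' @slot siteId character site identifiers.
#' @slot siteCovs data.frame of site-level covariates (one row per site).
#' @slot replicateLength numeric replicate (segment) length in metres.
#' @slot transectLength numeric per-site surveyed road length in metres.
#' @export
setClass("DetectionHistorySet",
  representation(y = "matrix", siteId = "character", siteCovs = "data.frame",
                 replicateLength = "numeric", transectLength = "numeric"),
  validity = function(object) {
    n <- nrow(object@y)
    if (length(object@siteId) != n) return("siteId length must equal nrow(y)")
    if (nrow(object@siteCovs) && nrow(object@siteCovs) != n)
      return("siteCovs rows must equal nrow(y)")
    v <- object@y[!is.na(object@y)]
    if (length(v) && !all(v %in% c(0L, 1L))) return("detections must be 0/1")
    if (any(rowSums(!is.na(object@y)) < 1L)) return("every site needs >= 1 replicate")
    bad <- is.na(object@y[, 1L])
    if (any(bad)) return("histories must be left-aligned (NA only as right padding)")
    TRUE
  })

#' Fitted occupancy model
#'
#' Maximum-likelihood fit of one of the three supported observation models
#' (\code{"mackenzie"}, \code{"markov"}, \code{"royle_nichols"}), holding
#' link-scale estimates, their covariance, the log-likelihood and AICc.
#'
#' @slot kind model kind.
#' @slot estimates named numeric parameter vector on the link scale
#'   (log link for abundance coefficients, logit for probabilities).
#' @slot vcov covariance matrix from the inverse numerical Hessian.
#' @slot logLik maximised log-likelihood.
#' @slot aicc small-sample corrected AIC.
#' @slot nSites number of sites used.
#' @slot converged optimiser convergence flag.
#' @slot K Poisson truncation bound (Royle-Nichols only; 0 otherwise).
#' @slot lambdaCovariates names of site covariates entering the abundance
#'   (or occupancy) linear predictor.
#' @export
setClass("OccupancyFit",
  representation(kind = "character", estimates = "numeric", vcov = "matrix",
                 logLik = "numeric", aicc = "numeric", nSites = "integer",
                 converged = "logical", K = "integer",
                 lambdaCovariates = "character"),
  validity = function(object) {
    if (!object@kind %in% c("mackenzie", "markov", "royle_nichols"))
      return("unknown model kind")
    TRUE
  })

#' Kernel utilization distribution and home range
#'
#' Per individual-season utilization distribution (probability mass per
#' cell, summing to 1) with its bandwidth matrix, the level-set home range
#' (isopleth) and the demographic class of the animal.
#'
#' @slot id individual identifier.
#' @slot season season identifier (e.g. \code{"2013"} for Apr-Oct 2013).
#' @slot demographicClass one of adult/subadult x female/male.
#' @slot ud [RasterGrid-class] of probability mass per cell.
#' @slot H 2x2 bandwidth matrix (m^2).
#' @slot isoLevel isopleth level (default 0.95).
#' @slot isoMask logical matrix marking cells inside the isopleth.
#' @slot isoPolygons list of closed rings (two-column coordinate matrices).
#' @slot nComponents number of disjoint isopleth components (contiguity flag).
#' @slot nFixes number of fixes behind the estimate.
#' @export
setClass("UtilizationDistribution",
  representation(id = "character", season = "character",
                 demographicClass = "character", ud = "RasterGrid",
                 H = "matrix", isoLevel = "numeric", isoMask = "matrix",
                 isoPolygons = "list", nComponents = "integer",
                 nFixes = "integer"),
  validity = function(object) {
    tot <- sum(object@ud@values)
    if (abs(tot - 1) > 1e-6) return("UD mass must sum to 1 (+-1e-6)")
    if (any(object@ud@values < 0)) return("UD mass must be non-negative")
    if (!identical(dim(object@isoMask), dim(object@ud@values)))
      return("isopleth mask must match the UD grid")
    TRUE
  })

#' Used-available resource selection design
#'
#' Row-per-point table contrasting used telemetry locations (response 1)
#' with available locations (response 0) drawn uniformly inside each
#' range-season's home-range isopleth, with standardized covariates and the
#' grouping factors for mixed-model fitting.
#'
#' @slot data data.frame with columns \code{used}, \code{class},
#'   \code{individual}, \code{rangeSeason}, \code{x}, \code{y} and one
#'   column per covariate (standardized).
#' @slot standardization shared standardization record (layer, mean, sd).
#' @slot ratio available:used ratio (default 4).
#' @slot covariates covariate column names.
#' @export
setClass("RSFDesign",
  representation(data = "data.frame", standardization = "data.frame",
                 ratio = "numeric", covariates = "character"),
  validity = function(object) {
    need <- c("used", "class", "individual", "rangeSeason")
    if (!all(need %in% names(object@data)))
      return("design data must have used, class, individual, rangeSeason")
    if (!all(object@data$used %in% c(0L, 1L))) return("used must be 0/1")
    TRUE
  })

#' Fitted logistic mixed-effects resource selection function
#'
#' Wraps the fitted model object with the fixed-effect table, random-effect
#' variance components and fit statistics used downstream for reporting and
#' mapping.
#'
#' @slot model the underlying fit (\code{glmerMod} from lme4, or \code{glm}
#'   when the random structure is empty).
#' @slot fixed data.frame with columns \code{term}, \code{beta}, \code{se},
#'   \code{z}, \code{p}.
#' @slot reVar named numeric vector of random-effect variances.
#' @slot logLik,aic numeric fit statistics.
#' @slot converged,singular logical flags.
#' @slot fixedFormula,randomTerms character records of the specification.
#' @export
setClass("GLMMFit",
  representation(model = "ANY", fixed = "data.frame", reVar = "numeric",
                 logLik = "numeric", aic = "numeric", converged = "logical",
                 singular = "logical", fixedFormula = "character",
                 randomTerms = "character"))
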