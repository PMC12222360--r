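#' Synthetic landscape configuration
#'
#' Bundles the grid geometry, feature counts and per-layer spatial-field
#' parameters for [generateLandscape()].  Each base covariate layer
#' (precipitation, NDVI, canopy) is a Gaussian random field (smoothed white
#' noise with a controllable correlation range) plus an optional linear
#' trend running SW to NE, min-max rescaled to the layer's value range.
#'
#' Defaults emulate a semi-arid savannah mosaic: mean annual precipitation
#' rising from 400 mm in the southwest to 680 mm in the northeast, NDVI in
#' [0, 1] and percent canopy cover in [0, 100] with shorter-range spatial
#' structure.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param cellsize cell size (m; default 1000).
#' @param xmin,ymin extent origin (m).
#' @param seed integer seed for all landscape randomness.
#' @param nSettlements,nWaterholes feature counts.
#' @param river optional polyline coordinate matrix; \code{NULL} draws a
#'   default channel across the northern third; \code{NA} omits the river.
#' @param layers named list of per-layer parameter lists with elements
#'   \code{min}, \code{max} (value range), \code{trend} (linear trend
#'   weight), \code{noise} (random-field weight), \code{range}
#'   (correlation range, m) and optional \code{trendDir} (\code{"swne"},
#'   the default, or \code{"nwse"}).
#' @return a \code{LandscapeConfig} (named list, class-tagged).
#' @export
landscapeConfig <- function(nrow = 80, ncol = 80, cellsize = 1000,
                            xmin = 0, ymin = 0, seed = 1,
                            nSettlements = 25, nWaterholes = 60,
                            river = NULL,
                            layers = list(
                              precipitation = list(min = 400, max = 680,
                                                   trend = 1, noise = 0.4,
                                                   range = 8000),
                              ndvi = list(min = 0.05, max = 0.85, trend = 0,
                                          noise = 1, range = 3000),
                              canopy = list(min = 0, max = 90, trend = 0,
                                            noise = 1, range = 3000))) {
  if (nrow < 1 || ncol < 1) stop("non-positive grid dimensions")
  if (cellsize <= 0) stop("cell size must be positive")
  if (nSettlements < 0 || nWaterholes < 0) stop("feature counts must be >= 0")
  cfg <- list(grid = gridSpecify(nrow, ncol, xmin, ymin, cellsize),
              seed = as.integer(seed), nSettlements = nSettlements,
              nWaterholes = nWaterholes, river = river, layers = layers)
  class(cfg) <- "LandscapeConfig"
  cfg
}

## Gaussian random field: white noise convolved (circularly, via FFT) with
## a Gaussian kernel of the requested correlation range, rescaled to unit
## variance.  Range 0 returns the raw white noise.
gaussianRandomField <- function(nrow, ncol, rangeCells) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (rangeCells <= 0) return(z)
  ry <- seq_len(nrow) - 1L; ry <- pmin(ry, nrow - ry)
  rx <- seq_len(ncol) - 1L; rx <- pmin(rx, ncol - rx)
  K <- exp(-outer(ry^2, rx^2, "+") / (2 * rangeCells^2))
  K <- K / sum(K)
  sm <- Re(fft(fft(z) * fft(K), inverse = TRUE)) / (nrow * ncol)
  (sm - mean(sm)) / sd(as.vector(sm))
}

## Unit trend surface in [0, 1]: "swne" rises SW to NE, "nwse" NW to SE.
trendSurface <- function(g, dir = "swne") {
  xn <- (seq_len(g@ncol) - 0.5) / g@ncol
  yn <- rev((seq_len(g@nrow) - 0.5) / g@nrow)  # row 1 = north = high
  if (dir == "nwse") yn <- 1 - yn
  (outer(yn, xn, "+")) / 2
}

#' Generate a synthetic landscape
#'
#' Produces the base covariate rasters (precipitation with a SW-NE
#' gradient, NDVI, canopy cover), settlement points with household counts,
#' waterhole points and an optional river polyline.  Bit-identical output
#' for a fixed configuration seed.
#'
#' @param config a [landscapeConfig()].
#' @return list with elements \code{stack} ([CovariateStack-class]),
#'   \code{settlements} (matrix x, y plus \code{households} attribute
#'   column), \code{waterholes} (matrix x, y), \code{river} (polyline
#'   matrix or NULL).
#' @export
generateLandscape <- function(config) {
  g <- config$grid
  withSeed(config$seed, {
    layers <- list()
    for (nm in names(config$layers)) {
      p <- config$layers[[nm]]
      fld <- p$trend * trendSurface(g, p$trendDir %||% "swne")
      if (p$noise > 0)
        fld <- fld + p$noise * gaussianRandomField(g@nrow, g@ncol,
                                                   p$range / g@cellsize)
      rng <- range(fld)
      if (diff(rng) == 0) {
        fld[] <- (p$min + p$max) / 2
      } else {
        fld <- p$min + (p$max - p$min) * (fld - rng[1]) / diff(rng)
      }
      layers[[nm]] <- fld
    }
    W <- g@ncol * g@cellsize; H <- g@nrow * g@cellsize
    rpt <- function(n) cbind(x = g@xmin + runif(n) * W,
                             y = g@ymin + runif(n) * H)
    settlements <- rpt(config$nSettlements)
    households <- if (config$nSettlements > 0)
      1L + rpois(config$nSettlements, 30) else integer(0)
    waterholes <- rpt(config$nWaterholes)
    river <- config$river
    if (is.null(river)) {
      ## meandering channel across the northern third, west to east
      xs <- seq(g@xmin, g@xmin + W, length.out = 20)
      ys <- g@ymin + 0.8 * H + 0.06 * H * sin(seq(0, 3 * pi, length.out = 20)) +
        rnorm(20, 0, 0.01 * H)
      river <- cbind(x = xs, y = ys)
    } else if (length(river) == 1 && is.na(river)) {
      river <- NULL
    }
    list(stack = covariateStack(layers, g),
         settlements = cbind(settlements, households = households),
         waterholes = waterholes, river = river)
  })
}

#' Derive water and settlement covariate layers
#'
#' Adds the four feature-derived layers used throughout the analysis:
#' Euclidean distance to the nearest waterhole or river point
#' (\code{dist_water}), quartic-kernel water density (\code{water_density}),
#' distance to the nearest settlement (\code{dist_settlement}) and
#' quartic-kernel settlement density weighted by household counts scaled by
#' the mean household size (\code{settlement_density}).
#'
#' @param stack a [CovariateStack-class] to extend.
#' @param settlements settlement point matrix, optionally with a
#'   \code{households} column used for density weights.
#' @param waterholes waterhole point matrix.
#' @param river optional river polyline (discretized to points 100 m apart).
#' @param radius kernel radius for the density layers (m; default 10000).
#' @param householdSize mean household size scaling settlement weights
#'   (default 3.7).
#' @return the stack with the four layers appended.
#' @export
deriveFeatureLayers <- function(stack, settlements, waterholes, river = NULL,
                                radius = 10000, householdSize = 3.7) {
  g <- stack@grid
  riverPts <- if (!is.null(river)) discretizeLine(river, 100) else NULL
  waterPts <- rbind(waterholes[, 1:2, drop = FALSE], riverPts)
  stack@layers$dist_water <- distanceToFeatures(g, points = waterPts)@values
  stack@layers$water_density <- kernelDensity(g, waterPts, radius = radius)@values
  sp <- settlements[, 1:2, drop = FALSE]
  w <- if ("households" %in% colnames(settlements))
    settlements[, "households"] * householdSize else rep(1, nrow(sp))
  stack@layers$dist_settlement <- distanceToFeatures(g, points = sp)@values
  stack@layers$settlement_density <- kernelDensity(g, sp, weights = w,
                                                   radius = radius)@values
  validObject(stack)
  stack
}
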