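#' Discretize a polyline to evenly spaced points
#'
#' Rivers enter the water layers as a series of virtual waterholes spaced
#' along the channel; this resamples a polyline at a fixed spacing by arc
#' length (both endpoints always included).
#'
#' @param coords two-column coordinate matrix of polyline vertices (m).
#' @param spacing spacing between successive points (m; default 100).
#' @return two-column matrix of points along the line.
#' @export
discretizeLine <- function(coords, spacing = 100) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) return(coords)
  seg <- sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- unique(c(seq(0, total, by = spacing), total))
  cbind(x = approx(s, coords[, 1], xout = at)$y,
        y = approx(s, coords[, 2], xout = at)$y)
}

#' Euclidean distance-to-feature raster
#'
#' Distance (m) from every cell centre to the nearest feature point.
#' Polylines are discretized to points at \code{lineSpacing} before the
#' distance transform, so a river behaves as a chain of waterholes.
#'
#' @param grid a [GridSpec-class].
#' @param points optional two-column matrix of feature points (m).
#' @param lines optional list of polyline coordinate matrices.
#' @param lineSpacing discretization spacing for lines (m; default 100).
#' @return a [RasterGrid-class] of distances (m).
#' @export
distanceToFeatures <- function(grid, points = NULL, lines = NULL,
                               lineSpacing = 100) {
  pts <- points
  if (!is.null(lines))
    pts <- rbind(pts, do.call(rbind, lapply(lines, discretizeLine,
                                            spacing = lineSpacing)))
  if (is.null(pts) || nrow(pts) == 0) stop("empty feature set")
  cc <- cellCenters(grid)
  d2 <- rep(Inf, nrow(cc))
  ## chunk over feature points to bound memory on large feature sets
  chunk <- 512L
  for (i in seq(1L, nrow(pts), by = chunk)) {
    j <- min(i + chunk - 1L, nrow(pts))
    dx <- outer(cc[, 1], pts[i:j, 1], "-")
    dy <- outer(cc[, 2], pts[i:j, 2], "-")
    d2 <- pmin(d2, apply(dx * dx + dy * dy, 1L, min))
  }
  rasterGrid(matrix(sqrt(d2), grid@nrow, grid@ncol), grid)
}

#' Quartic (biweight) kernel density surface
#'
#' Weighted kernel density with the compact-support biweight kernel
#' \deqn{f(s) = \sum_i w_i \frac{3}{\pi h^2}\bigl(1 - (d_i/h)^2\bigr)^2, \quad d_i < h,}
#' where \eqn{h} is the kernel radius.  A unit-weight point contributes
#' total mass 1 (true density normalisation), so the integral of the
#' surface over the plane equals the sum of the weights.
#'
#' @param grid a [GridSpec-class].
#' @param points two-column matrix of feature points (m).
#' @param weights per-point weights (default 1); must be non-negative.
#' @param radius kernel radius \eqn{h} in metres (default 10000).
#' @return a [RasterGrid-class] of density (per m^2).
#' @export
kernelDensity <- function(grid, points, weights = NULL, radius = 10000) {
  if (radius <= 0) stop("radius must be positive")
  points <- as.matrix(points)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (any(weights < 0)) stop("negative weights")
  cc <- cellCenters(grid)
  dens <- numeric(nrow(cc))
  const <- 3 / (pi * radius^2)
  for (i in seq_len(nrow(points))) {
    dx <- cc[, 1] - points[i, 1]
    dy <- cc[, 2] - points[i, 2]
    d2 <- dx * dx + dy * dy
    inside <- d2 < radius^2
    u <- 1 - d2[inside] / radius^2
    dens[inside] <- dens[inside] + weights[i] * const * u * u
  }
  rasterGrid(matrix(dens, grid@nrow, grid@ncol), grid)
}

#' Standardize (z-score) covariate layers
#'
#' Centres and scales the named layers over their valid (non-NA) cells and
#' appends the per-layer mean and SD to the stack's standardization record
#' so fitted coefficients can be back-transformed and new points scored on
#' the fitting-time scale.  Already standardized layers are left unchanged
#' (idempotent).
#'
#' @param x a [CovariateStack-class].
#' @param layers layer names (default: all).
#' @return the stack with standardized layers and an updated record.
#' @name standardizeLayers
NULL

#' @describeIn standardizeLayers z-score layers of a stack
setMethod("standardizeLayers", "CovariateStack", function(x, layers = NULL) {
  if (is.null(layers)) layers <- names(x@layers)
  rec <- x@standardization
  for (nm in layers) {
    if (nm %in% rec$layer) next
    m <- getLayer(x, nm)
    mu <- mean(m, na.rm = TRUE)
    s <- sd(as.vector(m), na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero variance in layer '", nm, "'")
    x@layers[[nm]] <- (m - mu) / s
    rec <- rbind(rec, data.frame(layer = nm, mean = mu, sd = s))
  }
  x@standardization <- rec
  validObject(x)
  x
})

#' Apply a stored standardization record to raw covariate values
#'
#' @param values data.frame of raw covariate values (columns named as layers).
#' @param record standardization record (layer, mean, sd).
#' @return data.frame on the z-scale.
#' @export
applyStandardization <- function(values, record) {
  for (i in seq_len(nrow(record))) {
    nm <- record$layer[i]
    if (nm %in% names(values))
      values[[nm]] <- (values[[nm]] - record$mean[i]) / record$sd[i]
  }
  values
}

#' Pairwise-correlation screen with AICc tie-break
#'
#' Drops, from every pair of candidate columns whose absolute Pearson
#' correlation exceeds the threshold, the member with the higher (worse)
#' univariate AICc.  Violating pairs are processed in decreasing order of
#' |r| until none remains; ties on AICc drop the lexicographically later
#' name so the screen is deterministic.
#'
#' @param columns data.frame or matrix of candidate covariate columns.
#' @param aiccValues named numeric vector of per-column univariate AICc.
#' @param threshold |r| threshold (default 0.70).
#' @return character vector of retained column names.
#' @export
correlationScreen <- function(columns, aiccValues, threshold = 0.70) {
  columns <- as.data.frame(columns)
  nms <- names(columns)
  if (!all(nms %in% names(aiccValues)))
    stop("aiccValues must cover every column")
  keep <- nms
  repeat {
    if (length(keep) < 2) break
    cm <- abs(cor(columns[keep]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop <- if (aiccValues[a] > aiccValues[b]) a
            else if (aiccValues[b] > aiccValues[a]) b
            else sort(c(a, b))[2]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Iterative variance-inflation-factor pruning
#'
#' Computes \eqn{VIF_j = 1/(1 - R^2_j)} from regressing each column on the
#' others and repeatedly drops the largest-VIF column while the maximum is
#' at or above the threshold.  Singular regressions (perfect collinearity)
#' yield infinite VIF and are dropped first.
#'
#' @param columns data.frame or matrix of design columns.
#' @param threshold critical VIF (default 3).
#' @return list with \code{retained} (names) and \code{vif} (data.frame
#'   trace of dropped columns and final VIFs).
#' @export
vifPrune <- function(columns, threshold = 3) {
  columns <- as.data.frame(columns)
  if (ncol(columns) < 2) stop("need >= 2 columns")
  if (nrow(columns) <= ncol(columns)) stop("need more rows than columns")
  keep <- names(columns)
  trace <- data.frame(column = character(), vif = numeric(),
                      action = character())
  vifOne <- function(j, cols) {
    fit <- lm(stats::reformulate(setdiff(cols, j), response = j),
              data = columns)
    ## a perfect fit (duplicated column) is the expected VIF = Inf path
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(keep) < 2) break
    v <- vapply(keep, vifOne, 0, cols = keep)
    if (max(v) < threshold) {
      trace <- rbind(trace, data.frame(column = keep, vif = v,
                                       action = "retained"))
      break
    }
    worst <- keep[which.max(v)]
    trace <- rbind(trace, data.frame(column = worst, vif = max(v),
                                     action = "dropped"))
    keep <- setdiff(keep, worst)
  }
  if (length(keep) == 1)
    trace <- rbind(trace, data.frame(column = keep, vif = 1,
                                     action = "retained"))
  rownames(trace) <- NULL
  list(retained = keep, vif = trace)
}
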