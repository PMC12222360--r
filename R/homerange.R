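#' Clean raw telemetry to residential daily locations
#'
#' Three-step preprocessing of raw GPS fixes, per individual:
#' \enumerate{
#'   \item impossible movements: a greedy forward pass drops any fix whose
#'     step speed from the last retained fix exceeds \code{maxSpeed};
#'   \item daily subsampling: within each day the fix closest to local
#'     noon is kept;
#'   \item residency: the net squared displacement over a sliding
#'     \code{residencyWindow}-day window is compared with its
#'     individual-level median, and fixes inside windows exceeding
#'     \code{residencyMult} times the median (dispersal excursions) are
#'     removed;
#'   \item the Apr-Oct dry-season window is retained.
#' }
#'
#' @param fixes data.frame with columns \code{individual}, \code{timestamp}
#'   (ISO-8601), \code{x}, \code{y} and any identity columns (carried
#'   through).
#' @param maxSpeed impossible-movement threshold (m/h; default 10000).
#' @param residencyWindow sliding window (days; default 14).
#' @param residencyMult multiple of the median windowed NSD flagging
#'   dispersal (default 10; the windowed NSD of a resident animal is
#'   roughly exponential, so a resident track exceeds 10x its median in
#'   well under 1% of windows while a range shift of several home-range
#'   diameters exceeds it immediately).
#' @param seasonMonths months retained (default April-October).
#' @return the cleaned data.frame (one fix per individual-day) with an
#'   added \code{season} column (calendar year of the dry season).
#' @export
preprocessTelemetry <- function(fixes, maxSpeed = 10000,
                                residencyWindow = 14, residencyMult = 10,
                                seasonMonths = 4:10) {
  tt <- as.POSIXct(fixes$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC")
  if (anyNA(tt)) stop("unparseable timestamps")
  fixes$.t <- tt
  out <- lapply(split(fixes, fixes$individual), function(f) {
    f <- f[order(f$.t), ]
    ## 1. impossible movements, greedy forward pass
    keep <- rep(TRUE, nrow(f))
    last <- 1L
    for (i in seq_len(nrow(f))[-1]) {
      dt <- as.numeric(difftime(f$.t[i], f$.t[last], units = "hours"))
      dd <- sqrt((f$x[i] - f$x[last])^2 + (f$y[i] - f$y[last])^2)
      if (dt > 0 && dd / dt > maxSpeed) keep[i] <- FALSE else last <- i
    }
    f <- f[keep, ]
    ## 2. one fix per day, closest to local noon
    day <- as.Date(f$.t)
    noonDist <- abs(as.numeric(format(f$.t, "%H")) +
                    as.numeric(format(f$.t, "%M")) / 60 - 12)
    f <- do.call(rbind, lapply(split(seq_len(nrow(f)), day), function(ix)
      f[ix[which.min(noonDist[ix])], ]))
    ## 3. residency: windowed net squared displacement vs its median
    if (nrow(f) > residencyWindow) {
      day <- as.Date(f$.t)
      nsd <- vapply(seq_len(nrow(f)), function(i) {
        j <- which(day > day[i] & day <= day[i] + residencyWindow)
        if (!length(j)) return(NA_real_)
        j <- j[length(j)]
        (f$x[j] - f$x[i])^2 + (f$y[j] - f$y[i])^2
      }, 0)
      med <- median(nsd, na.rm = TRUE)
      if (is.finite(med) && med > 0) {
        bad <- which(!is.na(nsd) & nsd > residencyMult * med)
        drop <- rep(FALSE, nrow(f))
        for (i in bad)
          drop[day >= day[i] & day <= day[i] + residencyWindow] <- TRUE
        f <- f[!drop, ]
      }
    }
    f
  })
  out <- do.call(rbind, out)
  out <- out[as.integer(format(out$.t, "%m")) %in% seasonMonths, ]
  out$season <- format(out$.t, "%Y")
  rownames(out) <- NULL
  out$.t <- NULL
  out
}

#' Demographic class from birth date and sex
#'
#' Subadult if and only if age at the season start is at most
#' \code{subadultAge} years (boundary inclusive); class is the sex by age
#' group combination.
#'
#' @param birthDate Date (or coercible) of birth; must precede the season
#'   start.
#' @param sex \code{"F"} or \code{"M"}.
#' @param seasonStart Date the dry season begins.
#' @param subadultAge age boundary in years (default 4).
#' @return one of \code{"adult female"}, \code{"subadult female"},
#'   \code{"adult male"}, \code{"subadult male"}.
#' @export
assignClass <- function(birthDate, sex, seasonStart, subadultAge = 4) {
  if (any(is.na(sex)) || !all(sex %in% c("F", "M"))) stop("missing sex")
  birthDate <- as.Date(birthDate); seasonStart <- as.Date(seasonStart)
  if (any(birthDate > seasonStart)) stop("birth date after season start")
  age <- as.numeric(seasonStart - birthDate) / 365.25
  grp <- ifelse(age <= subadultAge, "subadult", "adult")
  paste(grp, ifelse(sex == "F", "female", "male"))
}

#' Plug-in bandwidth matrix for a 2-D point sample
#'
#' Diagonal bandwidth matrix with separate per-axis bandwidths from the
#' univariate direct-plug-in pipeline (\code{KernSmooth::dpik}) applied
#' marginally; optionally the normal-reference rule
#' \eqn{H_{ii} = \sigma_i^2 n^{-1/3}}.
#'
#' @param points n x 2 coordinate matrix (m), n >= 30.
#' @param method \code{"plugin"} (default) or \code{"reference"}.
#' @return 2 x 2 positive-definite diagonal bandwidth matrix (m^2).
#' @export
pluginBandwidth <- function(points, method = c("plugin", "reference")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) < 30) stop("need at least 30 points")
  if (any(apply(points, 2, sd) == 0)) stop("degenerate point set")
  h2 <- if (method == "plugin") {
    c(KernSmooth::dpik(points[, 1]), KernSmooth::dpik(points[, 2]))^2
  } else {
    apply(points, 2, var) * nrow(points)^(-1 / 3)
  }
  diag(h2)
}

#' Kernel utilization distribution on a grid
#'
#' Gaussian-kernel density with (diagonal) bandwidth matrix \code{H},
#' evaluated at cell centres and renormalised to probability mass per cell
#' summing to 1.  Errors if more than 1% of the kernel mass falls outside
#' the grid (the extent is too small).
#'
#' @param points n x 2 coordinate matrix of fixes (m).
#' @param H 2 x 2 positive-definite bandwidth matrix; off-diagonal terms
#'   must be zero (separable evaluation).
#' @param grid a [GridSpec-class].
#' @return a [RasterGrid-class] of per-cell probability mass.
#' @export
kdeUD <- function(points, H, grid) {
  ev <- eigen(H, only.values = TRUE)$values
  if (any(ev <= 0)) stop("H must be positive-definite")
  if (any(abs(H[upper.tri(H)]) > 1e-12))
    stop("only diagonal bandwidth matrices are supported")
  points <- as.matrix(points)
  hx <- sqrt(H[1, 1]); hy <- sqrt(H[2, 2])
  gx <- gridXCenters(grid); gy <- gridYCenters(grid)
  ## separable Gaussian: density = (Ky %*% t(Kx)) / n, rows = y (north-first)
  Kx <- outer(gx, points[, 1], function(g, p) dnorm(g, p, hx))
  Ky <- outer(gy, points[, 2], function(g, p) dnorm(g, p, hy))
  dens <- (Ky %*% t(Kx)) / nrow(points)
  mass <- sum(dens) * grid@cellsize^2
  if (mass < 0.99)
    stop(sprintf(paste0("%.1f%% of the kernel mass falls outside the ",
                        "grid; enlarge the extent"), 100 * (1 - mass)))
  rasterGrid(dens / sum(dens), grid)
}

## Connected components (4-neighbour) of a logical matrix; returns the
## component count and a label matrix.
labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  idx <- which(mask & lab == 0L)
  while (length(idx)) {
    comp <- comp + 1L
    queue <- idx[1]
    lab[queue] <- comp
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nr + 1L; j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > ncol(mask)) next
        k <- (nb[2] - 1L) * nr + nb[1]
        if (mask[k] && lab[k] == 0L) { lab[k] <- comp; queue <- c(queue, k) }
      }
    }
    idx <- which(mask & lab == 0L)
  }
  list(n = comp, labels = lab)
}

## Trace the boundary of a cell mask into closed rings (map coordinates).
maskToPolygons <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  ymax <- grid@ymin + nr * grid@cellsize
  cs <- grid@cellsize
  ## collect boundary edges as vertex-index pairs on the (nc+1)x(nr+1)
  ## corner lattice; corner (cx, cy) with cx in 0..nc, cy in 0..nr (row top)
  edges <- list()
  vid <- function(cx, cy) cy * (nc + 1L) + cx + 1L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    if (i == 1L || !mask[i - 1L, j])          # top edge
      edges[[length(edges) + 1L]] <- c(vid(j - 1L, i - 1L), vid(j, i - 1L))
    if (i == nr || !mask[i + 1L, j])          # bottom
      edges[[length(edges) + 1L]] <- c(vid(j - 1L, i), vid(j, i))
    if (j == 1L || !mask[i, j - 1L])          # left
      edges[[length(edges) + 1L]] <- c(vid(j - 1L, i - 1L), vid(j - 1L, i))
    if (j == nc || !mask[i, j + 1L])          # right
      edges[[length(edges) + 1L]] <- c(vid(j, i - 1L), vid(j, i))
  }
  if (!length(edges)) return(list())
  em <- do.call(rbind, edges)
  used <- rep(FALSE, nrow(em))
  ## adjacency keyed by vertex id over both endpoints
  adj <- split(rep(seq_len(nrow(em)), 2), c(em[, 1], em[, 2]))
  toXY <- function(v) {
    v <- v - 1L
    cy <- v %/% (nc + 1L); cx <- v %% (nc + 1L)
    c(grid@xmin + cx * cs, ymax - cy * cs)
  }
  rings <- list()
  for (e0 in seq_len(nrow(em))) {
    if (used[e0]) next
    ring <- em[e0, 1]
    cur <- em[e0, 2]
    used[e0] <- TRUE
    ring <- c(ring, cur)
    repeat {
      nxt <- adj[[as.character(cur)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      e <- nxt[1]
      used[e] <- TRUE
      cur <- if (em[e, 1] == cur) em[e, 2] else em[e, 1]
      ring <- c(ring, cur)
      if (cur == ring[1]) break
    }
    coords <- do.call(rbind, lapply(ring, toXY))
    colnames(coords) <- c("x", "y")
    rings[[length(rings) + 1L]] <- coords
  }
  rings
}

#' Level-set isopleth of a utilization distribution
#'
#' Smallest set of cells whose summed mass reaches the level: cells are
#' ranked by density and cut at the cumulative level, which is the
#' minimal-area (highest-density) region among all cell sets of that mass.
#'
#' @param ud a [RasterGrid-class] of per-cell probability mass (sums to 1).
#' @param level isopleth level in (0, 1) (default 0.95).
#' @return list with \code{mask} (logical matrix), \code{polygons} (list
#'   of closed rings), \code{area} (m^2), \code{mass} (contained mass) and
#'   \code{nComponents}.
#' @export
isopleth <- function(ud, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  v <- as.vector(ud@values)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  nIn <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(ud@values), ncol(ud@values))
  mask[ord[seq_len(nIn)]] <- TRUE
  comp <- labelComponents(mask)
  list(mask = mask, polygons = maskToPolygons(mask, ud@grid),
       area = nIn * ud@grid@cellsize^2, mass = cum[nIn],
       nComponents = comp$n)
}

#' Utilization distribution and home range for one individual-season
#'
#' Convenience constructor running [pluginBandwidth()], [kdeUD()] and
#' [isopleth()] and packing the result into a
#' [UtilizationDistribution-class].
#'
#' @param points fix coordinates (n x 2, m).
#' @param id,season,demographicClass identity metadata.
#' @param grid optional [GridSpec-class]; by default a grid of about 150
#'   cells per axis padded 4 bandwidths beyond the fixes.
#' @param H optional bandwidth matrix (default plug-in).
#' @param level isopleth level (default 0.95).
#' @param bandwidthMethod forwarded to [pluginBandwidth()].
#' @return a [UtilizationDistribution-class].
#' @export
fitUD <- function(points, id = "animal", season = "1",
                  demographicClass = "adult female", grid = NULL, H = NULL,
                  level = 0.95, bandwidthMethod = "plugin") {
  points <- as.matrix(points)
  if (is.null(H)) H <- pluginBandwidth(points, method = bandwidthMethod)
  if (is.null(grid)) {
    pad <- 4 * sqrt(max(diag(H)))
    xr <- range(points[, 1]) + c(-pad, pad)
    yr <- range(points[, 2]) + c(-pad, pad)
    cs <- max(diff(xr), diff(yr)) / 150
    grid <- gridSpecify(ceiling(diff(yr) / cs), ceiling(diff(xr) / cs),
                        xr[1], yr[1], cs)
  }
  ud <- kdeUD(points, H, grid)
  iso <- isopleth(ud, level)
  new("UtilizationDistribution", id = as.character(id),
      season = as.character(season),
      demographicClass = demographicClass, ud = ud, H = H,
      isoLevel = level, isoMask = iso$mask, isoPolygons = iso$polygons,
      nComponents = as.integer(iso$nComponents),
      nFixes = as.integer(nrow(points)))
}

setMethod("show", "UtilizationDistribution", function(object) {
  cat(sprintf(paste0("UtilizationDistribution %s/%s (%s): %d fixes, ",
                     "%.0f%% isopleth area %.1f km^2 in %d component(s)\n"),
              object@id, object@season, object@demographicClass,
              object@nFixes, 100 * object@isoLevel,
              sum(object@isoMask) * object@ud@grid@cellsize^2 / 1e6,
              object@nComponents))
})

#' Home ranges for every individual-season with enough data
#'
#' Splits clean daily locations by individual and season, applies the
#' minimum-data rule (at least \code{minDays} distinct days, i.e. two
#' months), assigns the demographic class from birth date and sex at the
#' season start, and fits a [UtilizationDistribution-class] per
#' individual-season.
#'
#' @param clean cleaned daily-location table from [preprocessTelemetry()]
#'   (columns individual, sex, birth, timestamp, x, y, season).
#' @param minDays minimum distinct days (default 60).
#' @param level isopleth level (default 0.95).
#' @param subadultAge demographic boundary (years; default 4).
#' @param bandwidthMethod forwarded to [pluginBandwidth()].
#' @return named list of [UtilizationDistribution-class] objects keyed
#'   \code{individual.season}.
#' @export
homeRanges <- function(clean, minDays = 60, level = 0.95, subadultAge = 4,
                       bandwidthMethod = "plugin") {
  keys <- paste(clean$individual, clean$season, sep = ".")
  out <- list()
  for (key in unique(keys)) {
    f <- clean[keys == key, ]
    days <- unique(substr(f$timestamp, 1, 10))
    if (length(days) < minDays) next
    seasonStart <- as.Date(sprintf("%s-04-01", f$season[1]))
    cls <- assignClass(f$birth[1], f$sex[1], seasonStart,
                       subadultAge = subadultAge)
    out[[key]] <- fitUD(cbind(f$x, f$y), id = f$individual[1],
                        season = f$season[1], demographicClass = cls,
                        level = level, bandwidthMethod = bandwidthMethod)
  }
  out
}
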