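#' Ground-truth parameters for a synthetic prey species
#'
#' Log-linear abundance over covariates, \eqn{\lambda(x) = \exp(a_0 + a^T x)},
#' with per-individual detection probability \eqn{r}; optional two-state
#' Markov parameters \eqn{\theta_0, \theta_1} induce clustered detections
#' along consecutive road segments (for exercising replicate-length
#' selection).
#'
#' @param species species name.
#' @param a0 abundance intercept (log scale).
#' @param a named coefficient vector; names must be stack layer names.
#' @param r per-individual detection probability in [0, 1].
#' @param theta0,theta1 optional Markov local-presence parameters,
#'   \eqn{0 \le \theta_0 \le \theta_1 \le 1}.
#' @return a \code{PreyTruth} (named list, class-tagged).
#' @export
preyTruth <- function(species, a0 = 0, a = numeric(0), r = 0.3,
                      theta0 = NULL, theta1 = NULL) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  if (!is.null(theta0) || !is.null(theta1)) {
    if (is.null(theta0) || is.null(theta1))
      stop("theta0 and theta1 must be given together")
    if (theta0 < 0 || theta1 > 1 || theta0 > theta1)
      stop("need 0 <= theta0 <= theta1 <= 1")
  }
  if (length(a) && (is.null(names(a)) || any(!nzchar(names(a)))))
    stop("abundance coefficients must be named after layers")
  structure(list(species = species, a0 = a0, a = a, r = r,
                 theta0 = theta0, theta1 = theta1),
            class = "PreyTruth")
}

#' Expected-abundance surface for a prey truth
#'
#' \eqn{\lambda(x) = \exp(a_0 + a^T x)} evaluated per cell.
#'
#' @param stack a [CovariateStack-class] containing every layer named in
#'   the truth's coefficient vector.
#' @param truth a [preyTruth()].
#' @return a [RasterGrid-class] of strictly positive expected abundance.
#' @export
simulatePreySurface <- function(stack, truth) {
  g <- stack@grid
  eta <- matrix(truth$a0, g@nrow, g@ncol)
  for (nm in names(truth$a)) {
    if (!nm %in% names(stack@layers)) stop("unknown layer: ", nm)
    eta <- eta + truth$a[[nm]] * getLayer(stack, nm)
  }
  rasterGrid(exp(eta), g)
}

#' Default synthetic road network
#'
#' A grid of straight west-east transects, one through the centre of every
#' site-cell row, so that each site cell contains one full cell-width of
#' road.  This mirrors a systematic road-transect survey without
#' replicating any real geometry.
#'
#' @param grid landscape [GridSpec-class].
#' @param siteSize site grid cell size (m; default 8000).
#' @return list of polyline coordinate matrices.
#' @export
makeRoadNetwork <- function(grid, siteSize = 8000) {
  W <- grid@ncol * grid@cellsize
  H <- grid@nrow * grid@cellsize
  nRows <- floor(H / siteSize)
  lapply(seq_len(nRows), function(i) {
    y <- grid@ymin + (i - 0.5) * siteSize
    cbind(x = c(grid@xmin, grid@xmin + W), y = c(y, y))
  })
}

#' Simulate a replicated road-transect track survey
#'
#' Splits the road network into consecutive segments of
#' \code{replicateLength}, assigns each segment to the site-grid cell
#' containing its midpoint, draws a latent site abundance
#' \eqn{N \sim Poisson(\bar\lambda_{site})} and records per-segment
#' detections.  Under the default (Royle-Nichols) regime each segment
#' detects independently with probability \eqn{1 - (1-r)^N}.  When the
#' truth carries Markov parameters, detections instead arise from a
#' segment-level two-state presence chain within occupied sites
#' (\eqn{P(z_j=1|z_{j-1}=0)=\theta_0}, \eqn{P(z_j=1|z_{j-1}=1)=\theta_1},
#' stationary start), with detection probability \eqn{1-(1-r)^N} given
#' local presence.
#'
#' @param lambda [RasterGrid-class] expected-abundance surface.
#' @param roads list of polyline coordinate matrices.
#' @param siteSize site grid cell size (m; default 8000).
#' @param replicateLength base segment length (m; default 2000).
#' @param truth a [preyTruth()] supplying \code{r} (and optionally
#'   \code{theta0}, \code{theta1}).
#' @param seed integer seed.
#' @return list with \code{records} (data.frame site, replicate,
#'   detection), \code{sites} (data.frame site, x, y, transectLength,
#'   lambda, N) and \code{replicateLength}.
#' @export
simulateTrackSurvey <- function(lambda, roads, siteSize = 8000,
                                replicateLength = 2000, truth, seed = 1) {
  if (replicateLength <= 0) stop("replicate length must be positive")
  if (is.null(roads) || length(roads) == 0) stop("empty road network")
  g <- lambda@grid
  ## midpoints of consecutive replicate segments along each road, in order
  segs <- list()
  for (rd in seq_along(roads)) {
    m <- as.matrix(roads[[rd]])
    seglen <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    total <- sum(seglen)
    nSeg <- floor(total / replicateLength)  # trailing remainder discarded
    if (nSeg < 1) next
    s <- c(0, cumsum(seglen))
    mid <- (seq_len(nSeg) - 0.5) * replicateLength
    segs[[rd]] <- cbind(x = approx(s, m[, 1], xout = mid)$y,
                        y = approx(s, m[, 2], xout = mid)$y)
  }
  mids <- do.call(rbind, segs)
  if (is.null(mids) || nrow(mids) == 0)
    stop("roads shorter than one replicate")
  sCol <- floor((mids[, 1] - g@xmin) / siteSize)
  sRow <- floor((mids[, 2] - g@ymin) / siteSize)
  siteId <- sprintf("s%03d_%03d", sRow, sCol)
  lamMid <- extractValues(lambda, mids)
  ord <- order(siteId)  # scan order; segment order preserved within site
  siteId <- siteId[ord]; mids <- mids[ord, , drop = FALSE]
  lamMid <- lamMid[ord]
  keep <- !is.na(lamMid)
  siteId <- siteId[keep]; mids <- mids[keep, , drop = FALSE]
  lamMid <- lamMid[keep]

  withSeed(seed, {
    sites <- unique(siteId)
    recs <- vector("list", length(sites))
    info <- vector("list", length(sites))
    for (k in seq_along(sites)) {
      idx <- which(siteId == sites[k])
      J <- length(idx)
      lam <- mean(lamMid[idx])
      N <- rpois(1, lam)
      pDet <- 1 - (1 - truth$r)^N
      if (is.null(truth$theta0)) {
        y <- rbinom(J, 1, pDet)
      } else if (N == 0) {
        y <- integer(J)
      } else {
        th0 <- truth$theta0; th1 <- truth$theta1
        pi0 <- if (th0 + (1 - th1) > 0) th0 / (th0 + (1 - th1)) else 1
        z <- integer(J)
        z[1] <- rbinom(1, 1, pi0)
        for (j in seq_len(J - 1))
          z[j + 1] <- rbinom(1, 1, if (z[j] == 1) th1 else th0)
        y <- rbinom(J, 1, pDet * z)
      }
      recs[[k]] <- data.frame(site = sites[k], replicate = seq_len(J),
                              detection = as.integer(y))
      info[[k]] <- data.frame(site = sites[k],
                              x = mean(mids[idx, 1]), y = mean(mids[idx, 2]),
                              transectLength = J * replicateLength,
                              lambda = lam, N = N)
    }
    list(records = do.call(rbind, recs), sites = do.call(rbind, info),
         replicateLength = replicateLength)
  })
}
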