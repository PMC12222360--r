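#' Ground-truth parameters for synthetic lion telemetry
#'
#' Class-specific exponential selection coefficients over standardized
#' covariates, with bivariate-Gaussian home-range kernels.  Within a home
#' range the fix intensity is \eqn{\propto \exp(\beta_c^T x(s)) \cdot
#' k(s - centre)} where \eqn{k} is an isotropic Gaussian of scale
#' \code{kernelSd}, so the downstream used-available logistic model targets
#' exactly \eqn{\beta_c}.
#'
#' @param betaByClass named list (one element per demographic class, all
#'   four of adult female / subadult female / adult male / subadult male)
#'   of named coefficient vectors over stack layers.
#' @param kernelSd home-range Gaussian kernel scale (m; default 6000).
#' @param fixesPerDay daily fix count (default 1).
#' @param year calendar year carrying the Apr-Oct dry season.
#' @return a \code{TelemetryTruth} (named list, class-tagged).
#' @export
telemetryTruth <- function(betaByClass, kernelSd = 6000, fixesPerDay = 1,
                           year = 2013) {
  classes <- c("adult female", "subadult female", "adult male",
               "subadult male")
  if (!setequal(names(betaByClass), classes))
    stop("betaByClass must name exactly the four demographic classes")
  structure(list(betaByClass = betaByClass, kernelSd = kernelSd,
                 fixesPerDay = fixesPerDay, year = year,
                 seasonStart = as.Date(sprintf("%d-04-01", year)),
                 seasonEnd = as.Date(sprintf("%d-10-31", year))),
            class = "TelemetryTruth")
}

classSex <- function(cls) ifelse(grepl("female", cls), "F", "M")
classIsSubadult <- function(cls) grepl("subadult", cls)

#' Simulate GPS telemetry for four demographic classes
#'
#' Draws daily fixes per individual by exact rejection sampling: proposals
#' from the home-range Gaussian kernel, accepted with probability
#' \eqn{\exp(\beta^T x(s))} divided by its maximum over the grid (so no
#' proposal can exceed the cap).  Birth dates are generated consistent
#' with each class (subadults 2.5-4 y, adults 5-11 y at season start) and
#' timestamps are jittered around local noon within the Apr-Oct window.
#'
#' @param stack a [CovariateStack-class]; the layers named in the truth's
#'   coefficient vectors must be present (standardized layers recommended).
#' @param truth a [telemetryTruth()].
#' @param nPerClass individuals per demographic class.
#' @param seed integer seed.
#' @param centers optional matrix of home-range centres (one row per
#'   individual, class-blocked in truth's class order); random otherwise,
#'   kept \code{2 kernelSd} inside the extent.
#' @return list with \code{fixes} (data.frame individual, class, sex,
#'   birth, timestamp, x, y) and \code{truth}.
#' @export
simulateTelemetry <- function(stack, truth, nPerClass = 3, seed = 1,
                              centers = NULL) {
  g <- stack@grid
  classes <- names(truth$betaByClass)
  layersNeeded <- unique(unlist(lapply(truth$betaByClass, names)))
  if (!all(layersNeeded %in% names(stack@layers)))
    stop("unknown layer in selection coefficients")
  cc <- cellCenters(g)
  X <- as.matrix(extractValues(stack, cc, layersNeeded))
  days <- seq(truth$seasonStart, truth$seasonEnd, by = "day")
  W <- g@ncol * g@cellsize; H <- g@nrow * g@cellsize
  pad <- min(2 * truth$kernelSd, 0.4 * min(W, H))

  withSeed(seed, {
    out <- list(); ind <- 0L
    for (cls in classes) {
      beta <- truth$betaByClass[[cls]]
      eta <- as.vector(X[, names(beta), drop = FALSE] %*% beta)
      etaMax <- max(eta, na.rm = TRUE)
      if (!is.finite(etaMax) || all(!is.finite(eta)))
        stop("degenerate selection intensity")
      for (i in seq_len(nPerClass)) {
        ind <- ind + 1L
        ctr <- if (!is.null(centers)) centers[ind, 1:2] else
          c(g@xmin + pad + runif(1) * (W - 2 * pad),
            g@ymin + pad + runif(1) * (H - 2 * pad))
        ageYears <- if (classIsSubadult(cls)) runif(1, 2.5, 4) else
          runif(1, 5, 11)
        birth <- truth$seasonStart - round(ageYears * 365.25)
        nFix <- length(days) * truth$fixesPerDay
        pts <- matrix(NA_real_, nFix, 2)
        got <- 0L; tries <- 0L
        while (got < nFix) {
          tries <- tries + 1L
          if (tries > 2000L * nFix) stop("rejection sampling degenerate")
          nProp <- (nFix - got) * 4L
          prop <- cbind(rnorm(nProp, ctr[1], truth$kernelSd),
                        rnorm(nProp, ctr[2], truth$kernelSd))
          xv <- extractValues(stack, prop, names(beta))
          etaP <- as.matrix(xv) %*% beta
          ok <- !is.na(etaP) & runif(nProp) < exp(etaP - etaMax)
          ok[is.na(ok)] <- FALSE
          nTake <- min(sum(ok), nFix - got)
          if (nTake > 0) {
            pts[(got + 1):(got + nTake), ] <-
              prop[which(ok)[seq_len(nTake)], , drop = FALSE]
            got <- got + nTake
          }
        }
        ts <- rep(days, each = truth$fixesPerDay)
        hour <- 12 + round(rnorm(nFix, 0, 1.5), 2)
        stamp <- as.POSIXct(ts, tz = "UTC") + hour * 3600
        out[[ind]] <- data.frame(
          individual = sprintf("lion%03d", ind), class = cls,
          sex = classSex(cls), birth = birth,
          timestamp = format(stamp, "%Y-%m-%dT%H:%M:%SZ"),
          x = pts[, 1], y = pts[, 2])
      }
    }
    list(fixes = do.call(rbind, out), truth = truth)
  })
}
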