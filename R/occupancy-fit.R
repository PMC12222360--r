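## Maximum-likelihood fitting of the occupancy observation models with
## multi-start quasi-Newton optimisation.

occParamNames <- function(kind, covariates, rCovariate = NULL) {
  switch(kind,
    mackenzie = c("psi(logit)", "p(logit)"),
    markov = c("psi(logit)", "theta0(logit)", "theta1(logit)", "p(logit)",
               "pi0(logit)"),
    royle_nichols = c("lambda(Int)",
                      if (length(covariates)) paste0("lambda(", covariates, ")"),
                      "r(logit)",
                      if (!is.null(rCovariate)) paste0("r(", rCovariate, ")")))
}

occStart <- function(kind, dh, covariates, rCovariate = NULL) {
  y <- dh@y
  naiveOcc <- mean(rowSums(y, na.rm = TRUE) > 0)
  naiveOcc <- min(max(naiveOcc, 0.05), 0.95)
  naiveDet <- mean(y[rowSums(y, na.rm = TRUE) > 0, ], na.rm = TRUE)
  naiveDet <- min(max(naiveDet, 0.05, na.rm = TRUE), 0.95)
  switch(kind,
    mackenzie = c(logit(naiveOcc), logit(naiveDet)),
    markov = c(logit(naiveOcc), logit(naiveDet), logit(naiveDet),
               logit(0.7), logit(naiveDet)),
    royle_nichols = c(log(-log(1 - naiveOcc) + 0.05),
                      rep(0, length(covariates)),
                      logit(0.3),
                      if (!is.null(rCovariate)) 0))
}

#' Fit an occupancy model by maximum likelihood
#'
#' Quasi-Newton (BFGS, numerical gradients) optimisation of
#' [nllMackenzie()], [nllMarkov()] or [nllRoyleNichols()], with jittered
#' multi-starts taking the best converged optimum, covariance from the
#' inverse numerical Hessian, and AICc.
#'
#' @param kind one of \code{"mackenzie"}, \code{"markov"},
#'   \code{"royle_nichols"}.
#' @param dh a [DetectionHistorySet-class].
#' @param covariates site covariates on the abundance predictor
#'   (Royle-Nichols only).
#' @param K Poisson truncation bound (Royle-Nichols; \code{NULL} =
#'   adaptive).
#' @param rCovariate optional detection covariate name (Royle-Nichols).
#' @param nStarts number of jittered starts (default 3).
#' @param start optional explicit start vector (used as the first start).
#' @param seed seed for start jitter.
#' @return an [OccupancyFit-class]; non-convergence of every start yields
#'   a flagged fit with \code{AICc = Inf}.
#' @export
fitOccupancy <- function(kind = c("royle_nichols", "mackenzie", "markov"),
                         dh, covariates = character(0), K = NULL,
                         rCovariate = NULL, nStarts = 3, start = NULL,
                         seed = 1) {
  kind <- match.arg(kind)
  if (all(dh@y == 0, na.rm = TRUE))
    warning("no detections: parameters are weakly identified")
  nll <- switch(kind,
    mackenzie = function(p) nllMackenzie(p, dh),
    markov = function(p) nllMarkov(p, dh),
    royle_nichols = function(p) nllRoyleNichols(p, dh, covariates, K,
                                                rCovariate))
  base <- start %||% occStart(kind, dh, covariates, rCovariate)
  nms <- occParamNames(kind, covariates, rCovariate)
  best <- NULL
  withSeed(seed, {
    for (s in seq_len(nStarts)) {
      p0 <- if (s == 1) base else base + rnorm(length(base), 0, 0.5)
      fit <- tryCatch(
        optim(p0, nll, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit))
        fit <- tryCatch(optim(p0, nll, method = "Nelder-Mead",
                              control = list(maxit = 2000)),
                        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value) ||
          fit$value >= .NLL_PENALTY / 2) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  n <- nrow(dh@y)
  k <- length(base)
  if (is.null(best)) {
    return(new("OccupancyFit", kind = kind,
               estimates = setNames(rep(NA_real_, k), nms),
               vcov = matrix(NA_real_, k, k), logLik = -Inf, aicc = Inf,
               nSites = as.integer(n), converged = FALSE,
               K = as.integer(K %||% 0L), lambdaCovariates = covariates))
  }
  H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  else matrix(NA_real_, k, k)
  ## symmetrise against numerical asymmetry in the Hessian
  if (all(is.finite(V))) V <- (V + t(V)) / 2
  ll <- -best$value
  new("OccupancyFit", kind = kind, estimates = setNames(best$par, nms),
      vcov = V, logLik = ll, aicc = aiccValue(ll, k, n),
      nSites = as.integer(n), converged = best$convergence == 0,
      K = as.integer(K %||% 0L), lambdaCovariates = covariates)
}

#' AICc of a fit
#' @param object a fitted model object.
#' @name aicc
NULL
#' @describeIn aicc AICc of an occupancy fit
setMethod("aicc", "OccupancyFit", function(object) object@aicc)

#' Link-scale parameter estimates
#' @param object a fitted model object.
#' @name estimates
NULL
#' @describeIn estimates estimates of an occupancy fit
setMethod("estimates", "OccupancyFit", function(object) object@estimates)

#' Number of sites behind a fit or history set
#' @param object the object.
#' @name nSites
NULL
#' @describeIn nSites sites in an occupancy fit
setMethod("nSites", "OccupancyFit", function(object) object@nSites)

setMethod("show", "OccupancyFit", function(object) {
  cat(sprintf("OccupancyFit [%s]: %d sites, logLik %.3f, AICc %.3f%s\n",
              object@kind, object@nSites, object@logLik, object@aicc,
              if (object@converged) "" else " (NOT converged)"))
  se <- sqrt(pmax(diag(object@vcov), 0))
  print(data.frame(estimate = round(object@estimates, 4),
                   se = round(se, 4)))
})

#' Wald test table for an occupancy fit
#'
#' @param fit an [OccupancyFit-class].
#' @return data.frame with estimate, SE, z and two-sided p per parameter.
#' @export
waldTable <- function(fit) {
  se <- sqrt(pmax(diag(fit@vcov), 0))
  z <- fit@estimates / se
  data.frame(term = names(fit@estimates), estimate = fit@estimates,
             se = se, z = z, p = 2 * pnorm(-abs(z)), row.names = NULL)
}
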