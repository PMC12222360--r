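## Occupancy observation-model likelihoods.  All three take link-scale
## parameter vectors (log link for abundance coefficients, logit for
## probabilities) so optimisation is unconstrained, and operate on the
## NA-padded detection matrix of a DetectionHistorySet.

## Guard value returned when a site likelihood underflows to zero
## (e.g. a detection with r = 0): keeps the objective finite for optim.
.NLL_PENALTY <- 1e10

.dhMatrix <- function(dh) {
  y <- dh@y
  storage.mode(y) <- "double"
  y
}

#' Negative log-likelihood of the constant-detection occupancy model
#'
#' Single-season model without Markovian dependence: site likelihood
#' \deqn{L_i = \psi \prod_j p^{y_{ij}} (1-p)^{1-y_{ij}} + (1-\psi)\,[\forall j: y_{ij}=0].}
#'
#' @param params numeric vector \code{c(logit psi, logit p)}.
#' @param dh a [DetectionHistorySet-class].
#' @return negative log-likelihood (large finite penalty on underflow).
#' @export
nllMackenzie <- function(params, dh) {
  if (nrow(dh@y) == 0) stop("empty history set")
  psi <- invLogit(params[1]); p <- invLogit(params[2])
  y <- .dhMatrix(dh)
  J <- rowSums(!is.na(y))
  d <- rowSums(y, na.rm = TRUE)
  condL <- p^d * (1 - p)^(J - d)
  L <- psi * condL + (1 - psi) * (d == 0)
  if (any(L <= 0)) return(.NLL_PENALTY)
  -sum(log(L))
}

#' Negative log-likelihood of the Markov spatial-dependence occupancy model
#'
#' Within occupied sites, local presence along consecutive replicates
#' follows a two-state Markov chain (\eqn{P(z_j=1|z_{j-1}=0)=\theta_0},
#' \eqn{P(z_j=1|z_{j-1}=1)=\theta_1}, \eqn{P(z_1=1)=\pi_0}) and detection
#' is Bernoulli(\eqn{p z_j}); the site likelihood marginalises the chain
#' with the forward algorithm:
#' \deqn{L_i = \psi \sum_{z} P(y_i | z) P(z) + (1-\psi)\,[\forall j: y_{ij}=0].}
#'
#' @param params numeric vector
#'   \code{c(logit psi, logit theta0, logit theta1, logit p, logit pi0)}.
#' @param dh a [DetectionHistorySet-class].
#' @return negative log-likelihood.
#' @export
nllMarkov <- function(params, dh) {
  if (nrow(dh@y) == 0) stop("empty history set")
  psi <- invLogit(params[1]); th0 <- invLogit(params[2])
  th1 <- invLogit(params[3]); p <- invLogit(params[4])
  pi0 <- invLogit(params[5])
  y <- .dhMatrix(dh)
  n <- nrow(y)
  e0 <- function(yj) ifelse(yj == 1, 0, 1)     # P(y | z = 0)
  e1 <- function(yj) ifelse(yj == 1, p, 1 - p) # P(y | z = 1)
  a0 <- (1 - pi0) * e0(y[, 1])
  a1 <- pi0 * e1(y[, 1])
  if (ncol(y) > 1) for (j in 2:ncol(y)) {
    act <- !is.na(y[, j])
    if (!any(act)) break
    n0 <- (a0[act] * (1 - th0) + a1[act] * (1 - th1)) * e0(y[act, j])
    n1 <- (a0[act] * th0 + a1[act] * th1) * e1(y[act, j])
    a0[act] <- n0; a1[act] <- n1
  }
  allZero <- rowSums(y, na.rm = TRUE) == 0
  L <- psi * (a0 + a1) + (1 - psi) * allZero
  if (any(L <= 0)) return(.NLL_PENALTY)
  -sum(log(L))
}

## Smallest Poisson truncation bound with tail mass < tol at lambdaMax,
## floored at kFloor.
adaptiveK <- function(lambdaMax, kFloor = 50L, tol = 1e-8) {
  K <- kFloor
  while (ppois(K, lambdaMax, lower.tail = FALSE) >= tol && K < 10000L)
    K <- K * 2L
  K
}

#' Negative log-likelihood of the abundance-induced heterogeneity model
#'
#' Royle-Nichols model: latent site abundance \eqn{N_i \sim
#' Poisson(\lambda_i)} with \eqn{\log \lambda_i = x_i^T a}, and replicate
#' detection probability \eqn{1 - (1-r)^{N_i}}:
#' \deqn{L_i = \sum_{N=0}^{K} Pois(N;\lambda_i)\, (1-q_N)^{d_i}\, q_N^{J_i-d_i},
#'  \quad q_N = (1-r)^N,}
#' where \eqn{d_i} is the number of detections over the \eqn{J_i}
#' replicates.  The per-individual detection probability \eqn{r} may
#' optionally depend on a site-level detection covariate (e.g. replicate
#' count) through a logit-linear term.
#'
#' @param params numeric vector: abundance coefficients (intercept first,
#'   log link), then the logit-scale \eqn{r} intercept, then (if
#'   \code{rCovariate} is given) the \eqn{r} slope.
#' @param dh a [DetectionHistorySet-class].
#' @param covariates names of site covariates in the abundance predictor.
#' @param K Poisson truncation bound; \code{NULL} chooses the smallest
#'   bound with tail mass below \code{1e-8} at the largest site
#'   \eqn{\lambda} (floor 50).  An explicit K that leaves more tail mass
#'   than that is an error.
#' @param rCovariate optional name of a site covariate on detection.
#' @return negative log-likelihood.
#' @export
nllRoyleNichols <- function(params, dh, covariates = character(0), K = NULL,
                            rCovariate = NULL) {
  if (nrow(dh@y) == 0) stop("empty history set")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dh@siteCovs[covariates]))
  nA <- ncol(X)
  a <- params[seq_len(nA)]
  lam <- exp(as.vector(X %*% a))
  if (any(!is.finite(lam)) || max(lam) > 1e4) return(.NLL_PENALTY)
  rEta <- params[nA + 1]
  if (!is.null(rCovariate))
    rEta <- rEta + params[nA + 2] * dh@siteCovs[[rCovariate]]
  r <- invLogit(rEta)
  if (is.null(K)) {
    K <- adaptiveK(max(lam))
  } else if (ppois(K, max(lam), lower.tail = FALSE) >= 1e-8) {
    stop("K too small: Poisson tail mass at the largest site lambda ",
         "exceeds 1e-8; increase K")
  }
  y <- .dhMatrix(dh)
  J <- rowSums(!is.na(y))
  d <- rowSums(y, na.rm = TRUE)
  Ns <- 0:K
  ## site x N matrices; site likelihood depends on y only through (d, J)
  pois <- outer(lam, Ns, function(l, n) dpois(n, l))
  r <- rep(r, length.out = length(lam))
  q <- outer(1 - r, Ns, "^")          # (1-r_i)^N
  L <- rowSums(pois * (1 - q)^d * q^(J - d))
  if (any(L <= 0)) return(.NLL_PENALTY)
  -sum(log(L))
}

#' Derived occupancy from a Royle-Nichols abundance
#'
#' \eqn{\psi = 1 - e^{-\lambda}}, the probability a site holds at least one
#' individual.
#'
#' @param lambda expected abundance (vector or raster values).
#' @return occupancy probability on the same shape.
#' @export
derivedOccupancy <- function(lambda) 1 - exp(-lambda)
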