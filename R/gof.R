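## Parametric-bootstrap goodness of fit for occupancy fits: Pearson
## chi-square over observed vs expected detection-history frequencies,
## with histories pooled into cohorts by replicate count.

## Exact probability of each observed unique history under the fitted
## model, per site.  Returns the cohort-level expected frequency table.
.historyKey <- function(y) apply(y, 1L, function(r)
  paste(r[!is.na(r)], collapse = ""))

.expectedFreq <- function(fit, dh) {
  y <- dh@y
  J <- rowSums(!is.na(y))
  key <- .historyKey(y)
  est <- fit@estimates
  out <- list()
  for (Jc in sort(unique(J))) {
    inC <- which(J == Jc)
    uh <- unique(key[inC])
    hmat <- do.call(rbind, lapply(uh, function(s)
      as.integer(strsplit(s, "")[[1]])))
    dU <- rowSums(hmat)
    ## P(history | site) for each unique history x site in cohort
    P <- switch(fit@kind,
      mackenzie = {
        psi <- invLogit(est[1]); p <- invLogit(est[2])
        Pc <- psi * p^dU * (1 - p)^(Jc - dU) + (1 - psi) * (dU == 0)
        matrix(Pc, length(uh), length(inC))
      },
      markov = {
        psi <- invLogit(est[1]); th0 <- invLogit(est[2])
        th1 <- invLogit(est[3]); p <- invLogit(est[4])
        pi0 <- invLogit(est[5])
        fwd <- vapply(seq_len(nrow(hmat)), function(h) {
          a0 <- (1 - pi0) * (if (hmat[h, 1] == 1) 0 else 1)
          a1 <- pi0 * (if (hmat[h, 1] == 1) p else 1 - p)
          for (j in seq_len(Jc - 1) + 1) {
            e0 <- if (hmat[h, j] == 1) 0 else 1
            e1 <- if (hmat[h, j] == 1) p else 1 - p
            n0 <- (a0 * (1 - th0) + a1 * (1 - th1)) * e0
            n1 <- (a0 * th0 + a1 * th1) * e1
            a0 <- n0; a1 <- n1
          }
          a0 + a1
        }, 0)
        Pc <- psi * fwd + (1 - psi) * (dU == 0)
        matrix(Pc, length(uh), length(inC))
      },
      royle_nichols = {
        nA <- 1 + length(fit@lambdaCovariates)
        X <- cbind(1, as.matrix(dh@siteCovs[fit@lambdaCovariates]))
        lam <- exp(as.vector(X %*% est[seq_len(nA)]))[inC]
        r <- invLogit(est[nA + 1])
        K <- adaptiveK(max(lam))
        Ns <- 0:K
        pois <- outer(lam, Ns, function(l, n) dpois(n, l))  # site x N
        q <- outer(rep(1 - r, length(inC)), Ns, "^")
        ## history x site (vapply binds per-site results as columns);
        ## depends on the history only through d
        vapply(seq_along(inC), function(ii)
          vapply(dU, function(d)
            sum(pois[ii, ] * (1 - q[ii, ])^d * q[ii, ]^(Jc - d)), 0),
          numeric(length(uh)))
      })
    P <- matrix(P, nrow = length(uh))
    E <- rowSums(P)
    O <- vapply(uh, function(s) sum(key[inC] == s), 0)
    out[[as.character(Jc)]] <- data.frame(J = Jc, history = uh,
                                          observed = O, expected = E,
                                          nSitesCohort = length(inC))
  }
  do.call(rbind, out)
}

#' Pearson chi-square statistic for an occupancy fit
#'
#' Observed vs expected detection-history frequencies (pooled by replicate
#' count); unobserved histories enter through the leftover expected mass
#' of each cohort.
#'
#' @param fit an [OccupancyFit-class].
#' @param dh the [DetectionHistorySet-class] the fit was made on.
#' @return the chi-square statistic (attribute \code{table} holds the
#'   frequency table).
#' @export
pearsonChisq <- function(fit, dh) {
  tab <- .expectedFreq(fit, dh)
  chisq <- 0
  for (Jc in unique(tab$J)) {
    tc <- tab[tab$J == Jc, ]
    chisq <- chisq + sum((tc$observed - tc$expected)^2 / tc$expected) +
      max(tc$nSitesCohort[1] - sum(tc$expected), 0)
  }
  attr(chisq, "table") <- tab
  chisq
}

## Simulate a detection-history set from a fitted model (same sites,
## covariates and replicate structure).
simulateFromFit <- function(fit, dh) {
  y <- dh@y
  J <- rowSums(!is.na(y))
  n <- nrow(y)
  est <- fit@estimates
  ynew <- matrix(NA_integer_, n, ncol(y))
  if (fit@kind == "mackenzie") {
    psi <- invLogit(est[1]); p <- invLogit(est[2])
    occ <- rbinom(n, 1, psi)
    for (i in seq_len(n))
      ynew[i, seq_len(J[i])] <- rbinom(J[i], 1, p * occ[i])
  } else if (fit@kind == "markov") {
    psi <- invLogit(est[1]); th0 <- invLogit(est[2])
    th1 <- invLogit(est[3]); p <- invLogit(est[4]); pi0 <- invLogit(est[5])
    occ <- rbinom(n, 1, psi)
    for (i in seq_len(n)) {
      if (occ[i] == 0) { ynew[i, seq_len(J[i])] <- 0L; next }
      z <- integer(J[i]); z[1] <- rbinom(1, 1, pi0)
      for (j in seq_len(J[i] - 1))
        z[j + 1] <- rbinom(1, 1, if (z[j] == 1) th1 else th0)
      ynew[i, seq_len(J[i])] <- rbinom(J[i], 1, p * z)
    }
  } else {
    nA <- 1 + length(fit@lambdaCovariates)
    X <- cbind(1, as.matrix(dh@siteCovs[fit@lambdaCovariates]))
    lam <- exp(as.vector(X %*% est[seq_len(nA)]))
    r <- invLogit(est[nA + 1])
    N <- rpois(n, lam)
    for (i in seq_len(n))
      ynew[i, seq_len(J[i])] <- rbinom(J[i], 1, 1 - (1 - r)^N[i])
  }
  new("DetectionHistorySet", y = ynew, siteId = dh@siteId,
      siteCovs = dh@siteCovs, replicateLength = dh@replicateLength,
      transectLength = dh@transectLength)
}

#' Parametric-bootstrap goodness of fit
#'
#' Simulates \code{nBoot} datasets from the fitted model, refits each and
#' compares the observed Pearson chi-square with the bootstrap
#' distribution, yielding a p-value and the overdispersion ratio
#' \eqn{\hat c = \chi^2_{obs} / \overline{\chi^{2*}}}.
#'
#' @param fit a converged [OccupancyFit-class].
#' @param dh the fitted [DetectionHistorySet-class].
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{chisq}, \code{p}, \code{cHat},
#'   \code{bootChisq} and \code{nFailed}.
#' @export
gofBootstrap <- function(fit, dh, nBoot = 1000, seed = 1) {
  if (!fit@converged) stop("fit did not converge")
  obs <- as.numeric(pearsonChisq(fit, dh))
  boot <- rep(NA_real_, nBoot)
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      dhb <- simulateFromFit(fit, dh)
      if (all(dhb@y == 0, na.rm = TRUE)) next
      fb <- fitOccupancy(fit@kind, dhb, covariates = fit@lambdaCovariates,
                         nStarts = 1, start = fit@estimates,
                         seed = childSeed(seed, b))
      if (!fb@converged) next
      boot[b] <- as.numeric(pearsonChisq(fb, dhb))
    }
  })
  nFailed <- sum(is.na(boot))
  if (nFailed > 0.1 * nBoot)
    stop("bootstrap refit failure rate above 10% (", nFailed, "/", nBoot, ")")
  boot <- boot[!is.na(boot)]
  list(chisq = obs, p = mean(boot >= obs), cHat = obs / mean(boot),
       bootChisq = boot, nFailed = nFailed)
}
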