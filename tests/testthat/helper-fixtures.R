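## Shared fixture builders.  Everything is generated in code at test time.

## DetectionHistorySet from a (possibly NA-padded) 0/1 matrix.
mkDH <- function(ymat, siteCovs = NULL, replicateLength = 2000) {
  recs <- do.call(rbind, lapply(seq_len(nrow(ymat)), function(i) {
    J <- sum(!is.na(ymat[i, ]))
    data.frame(site = sprintf("s%03d", i), replicate = seq_len(J),
               detection = as.integer(ymat[i, seq_len(J)]))
  }))
  if (!is.null(siteCovs)) siteCovs$site <- sprintf("s%03d", seq_len(nrow(ymat)))
  buildDetectionHistories(recs, siteCovs, replicateLength)
}

## Detection histories simulated from Royle-Nichols truth.
simRNData <- function(nSites, J, a0, a1, r, seed) {
  set.seed(seed)
  x <- rnorm(nSites)
  lam <- exp(a0 + a1 * x)
  N <- rpois(nSites, lam)
  y <- matrix(rbinom(nSites * J, 1, rep(1 - (1 - r)^N, J)), nSites, J)
  mkDH(y, data.frame(x1 = x))
}

## Independent-oracle likelihoods, written against the model definitions
## rather than the package implementation.

## 2-state latent-occupancy enumeration for the constant-detection model.
oracleMackenzie <- function(psi, p, ymat) {
  ll <- 0
  for (i in seq_len(nrow(ymat))) {
    y <- ymat[i, !is.na(ymat[i, ])]
    Locc <- prod(p^y * (1 - p)^(1 - y))
    ll <- ll + log(psi * Locc + (1 - psi) * all(y == 0))
  }
  -ll
}

## Full path enumeration over the presence chain.
oracleMarkov <- function(psi, th0, th1, p, pi0, ymat) {
  ll <- 0
  for (i in seq_len(nrow(ymat))) {
    y <- ymat[i, !is.na(ymat[i, ])]
    J <- length(y)
    tot <- 0
    for (code in 0:(2^J - 1)) {
      z <- as.integer(intToBits(code)[seq_len(J)])
      pz <- if (z[1] == 1) pi0 else 1 - pi0
      if (J > 1) for (j in 2:J) {
        tr <- if (z[j - 1] == 1) th1 else th0
        pz <- pz * if (z[j] == 1) tr else 1 - tr
      }
      py <- prod(ifelse(y == 1, p * z, 1 - p * z))
      tot <- tot + pz * py
    }
    ll <- ll + log(psi * tot + (1 - psi) * all(y == 0))
  }
  -ll
}

## Truncated-sum Royle-Nichols with an explicit loop over N.
oracleRoyleNichols <- function(a0, a1, x, r, ymat, K = 200) {
  ll <- 0
  for (i in seq_len(nrow(ymat))) {
    y <- ymat[i, !is.na(ymat[i, ])]
    lam <- exp(a0 + if (length(x)) a1 * x[i] else 0)
    L <- 0
    for (N in 0:K) {
      pN <- 1 - (1 - r)^N
      L <- L + dpois(N, lam) * prod(pN^y * (1 - pN)^(1 - y))
    }
    ll <- ll + log(L)
  }
  -ll
}

## Hand-written iteratively reweighted least squares logistic fit, the
## independent oracle for the zero-variance mixed model.
irlsLogistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    betaNew <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  as.vector(beta)
}

## Used-available design simulated directly from a logistic mixed model
## (per-individual random intercept), for GLMM-level recovery tests.
simGlmmDesign <- function(seed, nInd = 12, nPerInd = 400,
                          beta = c(x1 = 0.5, x2 = -0.4), sdInt = 0.5,
                          interactionSM = 0) {
  set.seed(seed)
  cls <- rep(demographicClasses(), length.out = nInd)
  rows <- lapply(seq_len(nInd), function(i) {
    a <- rnorm(1, -1.4, sdInt)
    x <- matrix(rnorm(nPerInd * length(beta)), ncol = length(beta),
                dimnames = list(NULL, names(beta)))
    b <- beta
    if (cls[i] == "subadult male") b[1] <- b[1] + interactionSM
    y <- rbinom(nPerInd, 1, plogis(a + x %*% b))
    data.frame(used = y, class = cls[i], individual = sprintf("i%02d", i),
               rangeSeason = sprintf("i%02d.r1", i), x = 0, y2 = 0, x,
               check.names = FALSE)
  })
  d <- do.call(rbind, rows)
  names(d)[names(d) == "y2"] <- "y"
  d$class <- factor(d$class, levels = demographicClasses())
  new("RSFDesign", data = d,
      standardization = data.frame(layer = names(beta), mean = 0, sd = 1),
      ratio = 4, covariates = names(beta))
}

## Small two-layer landscape + telemetry truth used by the end-to-end
## recovery runs: fine-scale (cell-scale) covariate variation, home-range
## kernels well inside the extent, and a sign-flipped precipitation
## response for subadult males.
recoveryLandscape <- function(seed) {
  lc <- landscapeConfig(
    nrow = 120, ncol = 120, cellsize = 500, seed = seed,
    nSettlements = 0, nWaterholes = 0, river = NA,
    layers = list(
      precipitation = list(min = 400, max = 680, trend = 0.3, noise = 1,
                           range = 1000),
      ndvi = list(min = 0.05, max = 0.85, trend = 0, noise = 1,
                  range = 1000)))
  standardizeLayers(generateLandscape(lc)$stack)
}

recoveryTruth <- function() {
  telemetryTruth(list(
    "adult female" = c(precipitation = 0.6, ndvi = -0.5),
    "subadult female" = c(precipitation = 0.6, ndvi = -0.5),
    "adult male" = c(precipitation = 0.6, ndvi = -0.5),
    "subadult male" = c(precipitation = -0.7, ndvi = -0.5)),
    kernelSd = 6000)
}

## One end-to-end run: telemetry -> cleaning -> home ranges -> design ->
## GLMM with a precipitation x class interaction.
runRecovery <- function(seed, nPerClass = 3) {
  std <- recoveryLandscape(seed)
  tel <- simulateTelemetry(std, recoveryTruth(), nPerClass = nPerClass,
                           seed = seed + 1000)
  clean <- preprocessTelemetry(tel$fixes)
  uds <- homeRanges(clean, minDays = 60, bandwidthMethod = "reference")
  design <- buildDesign(uds, clean, std, c("precipitation", "ndvi"),
                        seed = seed)
  fit <- fitGlmm(design, classInteractions = "precipitation",
                 randomTerms = "(1 | individual)")
  list(design = design, fit = fit)
}
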