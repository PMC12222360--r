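test_that("constant-detection likelihood matches hand arithmetic and enumeration", {
  dh <- mkDH(matrix(c(0L, 0L), 1))
  expect_equal(nllMackenzie(c(qlogis(.5), qlogis(.5)), dh), -log(0.625),
               tolerance = 1e-10)
  dh11 <- mkDH(matrix(c(1L, 1L), 1))
  expect_equal(nllMackenzie(c(Inf, Inf), dh11), 0)
  ## brute-force latent-state enumeration on a ragged 5-site toy
  set.seed(1)
  y <- matrix(rbinom(20, 1, 0.4), 5, 4)
  y[1, 4] <- NA; y[3, 3:4] <- NA
  dh5 <- mkDH(y)
  for (par in list(c(0.3, -0.5), c(1.2, 0.8), c(-1, 2))) {
    expect_equal(nllMackenzie(par, dh5),
                 oracleMackenzie(plogis(par[1]), plogis(par[2]), y),
                 tolerance = 1e-8)
  }
  empty <- new("DetectionHistorySet", y = matrix(integer(0), 0, 1),
               siteId = character(0), siteCovs = data.frame(),
               replicateLength = 2000, transectLength = numeric(0))
  expect_error(nllMackenzie(c(0, 0), empty), "empty")
})

test_that("Markov likelihood equals path enumeration and degenerates correctly", {
  set.seed(2)
  y <- matrix(rbinom(20, 1, 0.4), 5, 4)
  y[2, 4] <- NA
  dh <- mkDH(y)
  ## J = 3 single-site check from the written-out 2^3 path sum
  dh3 <- mkDH(matrix(c(0L, 1L, 0L), 1))
  pars <- qlogis(c(0.7, 0.3, 0.8, 0.5, 0.4))
  expect_equal(nllMarkov(pars, dh3),
               oracleMarkov(0.7, 0.3, 0.8, 0.5, 0.4,
                            matrix(c(0L, 1L, 0L), 1)),
               tolerance = 1e-8)
  ## ragged multi-site
  for (pr in list(c(.6, .2, .7, .45, .5), c(.3, .5, .5, .8, .2))) {
    expect_equal(nllMarkov(qlogis(pr), dh),
                 oracleMarkov(pr[1], pr[2], pr[3], pr[4], pr[5], y),
                 tolerance = 1e-8)
  }
  ## theta0 = theta1 = pi0 = 1 collapses the chain onto constant detection
  par2 <- c(qlogis(0.6), qlogis(0.35))
  expect_equal(nllMarkov(c(par2[1], Inf, Inf, par2[2], Inf), dh),
               nllMackenzie(par2, dh), tolerance = 1e-12)
})

test_that("Royle-Nichols likelihood matches the truncated-sum oracle", {
  ## lambda = 1, r = 0.5, history (1, 0): frozen oracle value
  dh <- mkDH(matrix(c(1L, 0L), 1))
  oracleVal <- oracleRoyleNichols(0, 0, numeric(0), 0.5,
                                  matrix(c(1L, 0L), 1))
  expect_equal(exp(-oracleVal), 0.1342, tolerance = 5e-4)
  expect_equal(nllRoyleNichols(c(0, qlogis(0.5)), dh, K = 50), oracleVal,
               tolerance = 1e-8)
  ## covariate-dependent lambda on a ragged toy
  set.seed(3)
  y <- matrix(rbinom(20, 1, 0.5), 5, 4)
  y[4, 3:4] <- NA
  x <- rnorm(5)
  dhx <- mkDH(y, data.frame(x1 = x))
  for (par in list(c(0.2, 0.8, qlogis(0.3)), c(-0.5, -0.4, qlogis(0.6)))) {
    expect_equal(
      nllRoyleNichols(par, dhx, covariates = "x1"),
      oracleRoyleNichols(par[1], par[2], x, plogis(par[3]), y),
      tolerance = 1e-8)
  }
  ## r = 0 with a detection: impossible data, guarded to a large penalty
  expect_gte(nllRoyleNichols(c(0, -Inf), dh, K = 50), 1e9)
  ## an explicit K leaving visible tail mass is refused
  expect_error(nllRoyleNichols(c(log(50), qlogis(0.3)), dh, K = 50),
               "K too small")
  ## derived occupancy is monotone in lambda
  expect_true(all(diff(derivedOccupancy(seq(0.1, 5, 0.1))) > 0))
})

test_that("fitting recovers parameters and satisfies MLE properties", {
  dh <- simRNData(150, 8, a0 = 0, a1 = 0.8, r = 0.3, seed = 42)
  fit <- fitOccupancy("royle_nichols", dh, covariates = "x1")
  expect_true(fit@converged)
  ## log-likelihood at the optimum is at least that at the truth
  nllTruth <- nllRoyleNichols(c(0, 0.8, qlogis(0.3)), dh, "x1")
  expect_gte(fit@logLik, -nllTruth)
  ## loose single-seed recovery (the tight averaged check is elsewhere)
  expect_lt(abs(unname(fit@estimates["lambda(x1)"]) - 0.8), 0.4)
  ## AICc identity and AICc > AIC
  k <- length(fit@estimates); n <- nSites(dh)
  expect_equal(aicc(fit),
               -2 * fit@logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_gt(aicc(fit), -2 * fit@logLik + 2 * k)
  ## covariance is symmetric with positive diagonal
  expect_equal(fit@vcov, t(fit@vcov))
  expect_true(all(diag(fit@vcov) > 0))
  ## Wald table lines up with the estimates
  wt <- waldTable(fit)
  expect_equal(wt$estimate, unname(fit@estimates))
})

test_that("single-replicate histories identify only the psi * p product", {
  set.seed(7)
  psi <- 0.7; p <- 0.6
  y <- matrix(rbinom(400, 1, psi * p), ncol = 1)
  fit <- fitOccupancy("mackenzie", mkDH(y), seed = 3)
  est <- plogis(fit@estimates)
  ## the product matches its closed-form MLE (the detection frequency)
  expect_equal(unname(est[1] * est[2]), mean(y), tolerance = 0.05)
})
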