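## A compact fixture: one landscape, cleaned fixes, home ranges, design.
localDesignFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    std <- recoveryLandscape(101)
    tel <- simulateTelemetry(std, recoveryTruth(), nPerClass = 1,
                             seed = 77)
    clean <- preprocessTelemetry(tel$fixes)
    uds <- homeRanges(clean, minDays = 60, bandwidthMethod = "reference")
    design <- buildDesign(uds, clean, std, c("precipitation", "ndvi"),
                          seed = 3)
    cache <<- list(std = std, clean = clean, uds = uds, design = design)
    cache
  }
})

test_that("the used-available design honours the 1:4 ratio and the isopleth", {
  fx <- localDesignFixture()
  d <- designData(fx$design)
  for (key in unique(d$rangeSeason)) {
    dk <- d[d$rangeSeason == key, ]
    expect_equal(sum(dk$used == 0), 4 * sum(dk$used == 1))
    ## available points fall inside that range's isopleth cells
    u <- fx$uds[[key]]
    av <- dk[dk$used == 0, c("x", "y")]
    rc <- habsel:::pointToCell(u@ud@grid, as.matrix(av))
    inIso <- u@isoMask[cbind(rc[, "row"], rc[, "col"])]
    expect_true(all(inIso))
  }
  ## standardization record shared with the stack
  expect_equal(fx$design@standardization$layer,
               c("precipitation", "ndvi"))
  expect_equal(fx$design@standardization$mean,
               fx$std@standardization$mean[
                 match(c("precipitation", "ndvi"),
                       fx$std@standardization$layer)])
})

test_that("available points are uniform over the isopleth area", {
  ## a synthetic UD with a hand-made two-block mask via a fine Gaussian
  set.seed(6)
  g <- gridSpecify(40, 40, 0, 0, 250)
  pts <- matrix(rnorm(4000, 5000, 1200), ncol = 2)
  u <- fitUD(pts, id = "u1", season = "2013", grid = g,
             H = diag(c(500^2, 500^2)))
  days <- seq(as.POSIXct("2013-04-01 12:00", tz = "UTC"), by = "day",
              length.out = 70)
  clean <- data.frame(individual = "u1", sex = "F",
                      birth = as.Date("2005-01-01"),
                      timestamp = format(days, "%Y-%m-%dT%H:%M:%SZ"),
                      x = pts[1:70, 1], y = pts[1:70, 2], season = "2013")
  stack <- covariateStack(list(z = matrix(rnorm(1600), 40, 40)), g)
  design <- buildDesign(list(u1.2013 = u), clean, stack, "z", ratio = 40,
                        seed = 9)
  av <- designData(design)
  av <- av[av$used == 0, ]
  rc <- habsel:::pointToCell(g, as.matrix(av[, c("x", "y")]))
  counts <- table(factor(paste(rc[, 1], rc[, 2]),
                         levels = paste(which(u@isoMask, arr.ind = TRUE)[, 1],
                                        which(u@isoMask, arr.ind = TRUE)[, 2])))
  ## equal-area cells: counts ~ multinomial uniform
  chi <- suppressWarnings(stats::chisq.test(as.vector(counts)))
  expect_gt(chi$p.value, 0.01)
})

test_that("a zero-variance mixed model equals the IRLS logistic oracle", {
  d <- simGlmmDesign(21, nInd = 6, nPerInd = 300)
  fit <- fitGlmm(d, randomTerms = character(0))
  dd <- designData(d)
  X <- stats::model.matrix(~ x1 + x2 + class + x1:class + x2:class, dd)
  betaOracle <- irlsLogistic(X, dd$used)
  ## term order differs between the formula builder and the oracle matrix
  m <- match(colnames(X), fit@fixed$term)
  expect_false(anyNA(m))
  expect_equal(fit@fixed$beta[m], betaOracle, tolerance = 1e-6)
  ## flipping the response negates every coefficient
  d2 <- d; d2@data$used <- 1L - d2@data$used
  fit2 <- fitGlmm(d2, randomTerms = character(0))
  expect_equal(fit2@fixed$beta, -fit@fixed$beta, tolerance = 1e-6)
})

test_that("the mixed model recovers known coefficients across classes", {
  beta <- c(x1 = 0.5, x2 = -0.4, x3 = 0.3, x4 = -0.2)
  ests <- ses <- NULL
  for (seed in 1:3) {
    d <- simGlmmDesign(seed, nInd = 12, nPerInd = 400, beta = beta,
                       sdInt = 0.5)
    fit <- fitGlmm(d, classInteractions = character(0),
                   randomTerms = "(1 | individual)")
    fxT <- fit@fixed
    m <- match(names(beta), fxT$term)
    ests <- rbind(ests, fxT$beta[m])
    ses <- rbind(ses, fxT$se[m])
  }
  expect_true(all(abs(t(t(ests) - beta)) < 3 * ses))
  expect_gt(cor(colMeans(ests), beta), 0.95)
})

test_that("random-structure reduction prunes spurious slopes, keeps real intercepts", {
  ## truth: intercept variance 0.5, no slope variance
  hits <- 0
  for (seed in 1:3) {
    d <- simGlmmDesign(seed + 30, nInd = 10, nPerInd = 250, sdInt = 0.7)
    rr <- reduceReStructure(d, classInteractions = character(0),
                            slopes = c("x1", "x2"), group = "individual")
    if (rr$randomTerms == "(1 | individual)") hits <- hits + 1
  }
  expect_gte(hits, 2)  # slopes dropped, intercept retained
})

test_that("single-term deletions keep real interactions and report df = 3", {
  d <- simGlmmDesign(41, nInd = 12, nPerInd = 350, interactionSM = -1.2)
  lrt <- lrtTermDeletion(d, covariates = c("x1", "x2"),
                         classInteractions = c("x1", "x2"),
                         randomTerms = "(1 | individual)")
  tab <- lrt$table
  expect_equal(tab$df[tab$type == "interaction"], c(3, 3))
  expect_true(tab$retained[tab$term == "x1" & tab$type == "interaction"])
  ## x2 has no interaction in truth but a real main effect
  expect_false(tab$retained[tab$term == "x2" & tab$type == "interaction"])
  expect_true("x2" %in% lrt$covariates)
  expect_true("x1" %in% lrt$classInteractions)
})

test_that("odds ratios reproduce the reporting arithmetic", {
  expect_equal(round(oddsRatios(0.42, 0.09)$or, 2), 1.52)
  expect_equal(round(oddsRatios(0, 0.1)$or, 2), 1.00)
  expect_equal(round(oddsRatios(0.05, 0.10)$lower, 2), 0.86)
  o <- oddsRatios(c(0.42, -0.98), c(0.09, 0.12))
  expect_equal(o$formatted[1], "1.52 (1.28-1.82)")
  expect_true(all(o$lower < o$or & o$or < o$upper))
})

test_that("variance-partition R2 behaves at its boundaries", {
  d <- simGlmmDesign(51, nInd = 6, nPerInd = 200,
                     beta = c(x1 = 0, x2 = 0), sdInt = 0)
  fit0 <- fitGlmm(d, classInteractions = character(0),
                  randomTerms = character(0))
  ## forcing all coefficients to zero zeroes the marginal R2
  fitNull <- fit0
  fitNull@fixed$beta <- rep(0, nrow(fit0@fixed))
  r2 <- r2Nakagawa(fitNull, d)
  expect_equal(unname(r2["marginal"]), 0)
  ## no random variance: conditional equals marginal
  r2f <- r2Nakagawa(fit0, d)
  expect_equal(r2f[["marginal"]], r2f[["conditional"]])
  ## with random variance: conditional >= marginal
  dm <- simGlmmDesign(52, nInd = 10, nPerInd = 200, sdInt = 0.8)
  fitm <- fitGlmm(dm, classInteractions = character(0),
                  randomTerms = "(1 | individual)")
  r2m <- r2Nakagawa(fitm, dm)
  expect_gte(r2m[["conditional"]], r2m[["marginal"]])
})

test_that("per-class selection maps follow the fitted interaction signs", {
  fx <- localDesignFixture()
  fit <- fitGlmm(fx$design, classInteractions = "precipitation",
                 randomTerms = character(0))
  mp <- lapply(c("adult female", "subadult male"), function(cl)
    predictRsfMap(fit, fx$std, cl, fx$design))
  names(mp) <- c("af", "sm")
  ## scaled maps span [0, 1]
  for (m in mp) {
    expect_equal(min(m$scaled@values), 0)
    expect_equal(max(m$scaled@values), 1)
  }
  ## the raw maps differ between classes exactly by the interaction tilt
  fxTab <- fit@fixed
  bInt <- fxTab$beta[fxTab$term == "precipitation:classsubadult male"]
  bCls <- fxTab$beta[fxTab$term == "classsubadult male"]
  lr <- log(mp$sm$raw@values) - log(mp$af$raw@values)
  expect_equal(lr, bCls + bInt * getLayer(fx$std, "precipitation"),
               tolerance = 1e-10)
})
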