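test_that("distance rasters are exact for points and tight for lines", {
  g <- gridSpecify(10, 10, 0, 0, 100)
  ## cell centre coinciding with the feature
  d0 <- distanceToFeatures(g, points = cbind(250, 250))
  expect_equal(extractValues(d0, cbind(250, 250)), 0)
  ## 3-4-5 triangle
  d1 <- distanceToFeatures(g, points = cbind(50, 50))
  expect_equal(extractValues(d1, cbind(350, 450)), 500)
  expect_error(distanceToFeatures(g), "empty feature set")

  ## discretized river vs exact point-to-segment distance oracle
  g2 <- gridSpecify(30, 30, 0, 0, 200)
  line <- cbind(x = c(500, 3000, 5500), y = c(800, 3500, 1500))
  dApprox <- distanceToFeatures(g2, lines = list(line), lineSpacing = 100)
  segDist <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  cc <- cellCenters(g2)
  dExact <- apply(cc, 1, function(p)
    min(segDist(p, line[1, ], line[2, ]), segDist(p, line[2, ], line[3, ])))
  expect_lte(max(abs(as.vector(dApprox@values) - dExact)), 50)

  ## 1-Lipschitz in the cell-centre displacement
  v <- dApprox@values
  dx <- abs(v[, -1] - v[, -ncol(v)])
  dy <- abs(v[-1, ] - v[-nrow(v), ])
  expect_lte(max(dx, dy), 200 + 1e-9)
})

test_that("quartic kernel density has the right peak, support and mass", {
  g <- gridSpecify(60, 60, 0, 0, 500)
  h <- 10000
  kd <- kernelDensity(g, cbind(15000, 15000), radius = h)
  expect_equal(extractValues(kd, cbind(15000, 15000)), 3 / (pi * h^2),
               tolerance = 1e-6)
  ## unit mass within 2% by quadrature at 500 m cells
  expect_equal(sum(kd@values) * 500^2, 1, tolerance = 0.02)
  ## zero beyond the radius
  expect_equal(extractValues(kd, cbind(15000 + h + 250, 15000)), 0)
  expect_error(kernelDensity(g, cbind(0, 0), weights = -1), "negative")
  ## weights scale mass linearly
  kd2 <- kernelDensity(g, rbind(c(15000, 15000), c(14000, 16000)),
                       weights = c(2, 3), radius = h)
  expect_equal(sum(kd2@values) * 500^2, 5, tolerance = 0.02)
})

test_that("standardization is exact, idempotent and guarded", {
  g <- gridSpecify(2, 2, 0, 0, 1)
  stack <- covariateStack(list(a = matrix(0:3, 2, 2),
                               flat = matrix(1, 2, 2)), g)
  std <- standardizeLayers(stack, "a")
  va <- as.vector(getLayer(std, "a"))
  expect_equal(mean(va), 0, tolerance = 1e-12)
  expect_equal(sd(va), 1, tolerance = 1e-12)
  ## record supports re-application to raw values
  raw <- data.frame(a = 0:3)
  expect_equal(applyStandardization(raw, std@standardization)$a, va)
  ## idempotent
  std2 <- standardizeLayers(std, "a")
  expect_equal(getLayer(std2, "a"), getLayer(std, "a"), tolerance = 1e-12)
  expect_error(standardizeLayers(stack, "flat"), "zero variance")
})

test_that("correlation screen drops the weaker member of collinear pairs", {
  set.seed(5)
  x <- rnorm(100)
  cols <- data.frame(a = x, b = x, c = rnorm(100))
  keep <- correlationScreen(cols, c(a = 100, b = 102, c = 50))
  expect_setequal(keep, c("a", "c"))
  ## orthogonal columns all retained
  ortho <- data.frame(u = rnorm(200), v = rnorm(200), w = rnorm(200))
  expect_setequal(correlationScreen(ortho, c(u = 1, v = 2, w = 3)),
                  c("u", "v", "w"))
  expect_error(correlationScreen(cols, c(a = 1, b = 2)), "every column")
})

test_that("correlation screen result is valid and maximal", {
  set.seed(8)
  z <- rnorm(300)
  cols <- data.frame(a = z + 0.3 * rnorm(300), b = z + 0.3 * rnorm(300),
                     c = z + 0.3 * rnorm(300), d = rnorm(300))
  aiccs <- c(a = 10, b = 12, c = 11, d = 20)
  keep <- correlationScreen(cols, aiccs, threshold = 0.7)
  noViolation <- function(set) {
    if (length(set) < 2) return(TRUE)
    cm <- abs(cor(cols[set])); diag(cm) <- 0
    max(cm) <= 0.7
  }
  expect_true(noViolation(keep))
  ## maximal: re-adding any dropped column creates a violation
  for (dropped in setdiff(names(cols), keep))
    expect_false(noViolation(c(keep, dropped)))
  ## exhaustive check: some valid subset of this size exists, none larger
  sizes <- vapply(0:4, function(m) {
    any(vapply(combn(names(cols), m, simplify = FALSE), noViolation, TRUE))
  }, TRUE)
  expect_equal(length(keep), max(which(sizes)) - 1L)
})

test_that("VIF pruning reaches the threshold and flags duplicates first", {
  set.seed(9)
  ind <- as.data.frame(matrix(rnorm(1e4 * 4), ncol = 4))
  res <- vifPrune(ind, threshold = 3)
  expect_setequal(res$retained, names(ind))
  expect_true(all(res$vif$vif[res$vif$action == "retained"] < 1.1))
  ## duplicated column: infinite VIF, dropped first
  dup <- data.frame(a = ind[[1]], b = ind[[1]], c = ind[[2]])
  res2 <- vifPrune(dup)
  expect_equal(res2$vif$action[1], "dropped")
  expect_true(res2$vif$column[1] %in% c("a", "b"))
  expect_false(all(c("a", "b") %in% res2$retained))
  ## postcondition on a strongly collinear set
  z <- rnorm(500)
  col <- data.frame(p = z + 0.2 * rnorm(500), q = z + 0.2 * rnorm(500),
                    s = rnorm(500))
  res3 <- vifPrune(col, threshold = 3)
  fin <- res3$vif[res3$vif$action == "retained", ]
  expect_true(all(fin$vif < 3))
  expect_error(vifPrune(ind[, 1, drop = FALSE]), ">= 2 columns")
})
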