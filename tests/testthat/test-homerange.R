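mkFixes <- function(xy, times, id = "a", sex = "M",
                    birth = as.Date("2007-01-01")) {
  data.frame(individual = id, sex = sex, birth = birth,
             timestamp = format(times, "%Y-%m-%dT%H:%M:%SZ"),
             x = xy[, 1], y = xy[, 2])
}

test_that("telemetry preprocessing removes the right fixes", {
  t0 <- as.POSIXct("2013-05-01 12:00:00", tz = "UTC")
  ## impossible movement: 100 km in 1 h at a 10 km/h ceiling
  f <- mkFixes(rbind(c(0, 0), c(100000, 0), c(500, 0)),
               t0 + c(0, 3600, 7200))
  clean <- preprocessTelemetry(f)
  expect_equal(nrow(clean), 1)  # one day: jump removed, then one fix/day
  ## three fixes in one day: the one nearest noon is retained
  f3 <- mkFixes(rbind(c(0, 0), c(10, 0), c(20, 0)),
                as.POSIXct("2013-05-01", tz = "UTC") + c(6, 13, 20) * 3600)
  c3 <- preprocessTelemetry(f3)
  expect_equal(nrow(c3), 1)
  expect_equal(c3$x, 10)
  ## a stationary dry-season track passes through unchanged
  days <- seq(as.POSIXct("2013-05-01 12:00", tz = "UTC"), by = "day",
              length.out = 90)
  set.seed(1)
  fs <- mkFixes(cbind(rnorm(90, 0, 800), rnorm(90, 0, 800)), days)
  expect_equal(nrow(preprocessTelemetry(fs)), 90)
  ## a mid-track dispersal excursion is cut out
  shift <- c(rep(0, 40), seq(0, 60000, length.out = 10), rep(60000, 40))
  fd <- mkFixes(cbind(rnorm(90, shift, 500), rnorm(90, 0, 500)), days)
  cd <- preprocessTelemetry(fd)
  expect_lt(nrow(cd), 90)
  expect_error(preprocessTelemetry(transform(fs, timestamp = "nope")),
               "timestamps")
})

test_that("demographic classing applies the inclusive 4-year boundary", {
  s <- as.Date("2013-04-01")
  expect_equal(assignClass(s - round(3.9 * 365.25), "M", s),
               "subadult male")
  expect_equal(assignClass(s - 4 * 365.25, "F", s), "subadult female")
  expect_equal(assignClass(s - round(4.1 * 365.25), "M", s), "adult male")
  expect_error(assignClass(s - 1000, NA, s), "sex")
  expect_error(assignClass(s + 10, "F", s), "birth date")
})

test_that("plug-in bandwidths are symmetric, shrinking and equivariant", {
  set.seed(2)
  pts <- matrix(rnorm(2e4), ncol = 2)
  H <- pluginBandwidth(pts)
  h <- sqrt(diag(H))
  expect_lt(abs(h[1] - h[2]) / h[1], 0.1)
  expect_equal(H[1, 2], 0)
  ## bandwidth decreases with sample size
  H100 <- pluginBandwidth(pts[1:100, ])
  expect_gt(sqrt(H100[1, 1]), h[1])
  ## axis scaling by 2 scales that bandwidth by ~2
  H2 <- pluginBandwidth(cbind(2 * pts[, 1], pts[, 2]))
  expect_equal(sqrt(H2[1, 1]) / h[1], 2, tolerance = 0.05)
  expect_equal(sqrt(H2[2, 2]), h[2])
  expect_error(pluginBandwidth(pts[1:10, ]), "at least 30")
  expect_error(pluginBandwidth(cbind(rep(1, 50), rnorm(50))), "degenerate")
  ## reference rule fallback
  Hr <- pluginBandwidth(pts, method = "reference")
  expect_equal(sqrt(Hr[1, 1]), sd(pts[, 1]) * nrow(pts)^(-1 / 6),
               tolerance = 1e-10)
})

test_that("the grid KDE matches the Gaussian convolution closed form", {
  set.seed(3)
  sigma <- 1000
  n <- 1e4
  pts <- matrix(rnorm(2 * n, 0, sigma), ncol = 2)
  h <- 400
  g <- gridSpecify(80, 80, -8000, -8000, 200)
  ud <- kdeUD(pts, diag(c(h^2, h^2)), g)
  expect_equal(sum(ud@values), 1, tolerance = 1e-6)
  ## expected UD is N(0, (sigma^2 + h^2) I)
  s2 <- sigma^2 + h^2
  gx <- seq(-8000 + 100, 8000 - 100, by = 200)
  ref <- outer(dnorm(gx, 0, sqrt(s2)), dnorm(gx, 0, sqrt(s2)))
  ref <- ref / sum(ref)
  expect_lt(sum(abs(ud@values - ref)), 0.05)
  ## a tight cluster puts the mode at the centroid cell
  ptsC <- matrix(rnorm(200, 1500, 30), ncol = 2)
  udc <- kdeUD(ptsC, diag(c(200^2, 200^2)), g)
  peak <- which(udc@values == max(udc@values), arr.ind = TRUE)
  cc <- cellCenters(g)
  idx <- (peak[2] - 1) * 80 + peak[1]
  expect_lt(max(abs(cc[idx, ] - 1500)), 300)
  ## mass escaping the grid is an error
  expect_error(kdeUD(pts, diag(c(h^2, h^2)),
                     gridSpecify(10, 10, 0, 0, 200)), "enlarge")
})

test_that("isopleths are minimal level sets with consistent polygons", {
  sigma <- 3000
  g <- gridSpecify(150, 150, -22500, -22500, 300)
  gx <- seq(-22500 + 150, 22500 - 150, by = 300)
  dens <- outer(dnorm(gx, 0, sigma), dnorm(gx, 0, sigma))
  ud <- rasterGrid(dens / sum(dens), g)
  iso <- isopleth(ud, 0.95)
  ## contained mass in [level, level + largest cell mass]
  expect_gte(iso$mass, 0.95)
  expect_lte(iso$mass, 0.95 + max(ud@values))
  ## closed-form area of the 95% Gaussian level set
  expect_equal(iso$area, pi * qchisq(0.95, 2) * sigma^2, tolerance = 0.05)
  expect_equal(iso$nComponents, 1L)
  ## rings are closed and enclose exactly the masked area (shoelace)
  shoelace <- function(m) {
    x <- m[, 1]; y <- m[, 2]; n <- nrow(m)
    abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
  }
  expect_true(all(vapply(iso$polygons, function(p)
    all(p[1, ] == p[nrow(p), ]), TRUE)))
  expect_equal(sum(vapply(iso$polygons, shoelace, 0)), iso$area,
               tolerance = 1e-9)
  ## level just below 1 covers nearly all cells carrying mass
  isoAll <- isopleth(ud, 1 - 1e-9)
  expect_gt(sum(isoAll$mask), 0.95 * sum(ud@values > 1e-12))
  expect_error(isopleth(ud, 1.2), "level")
})

test_that("the density-ranked cut is optimal among cell subsets", {
  set.seed(4)
  v <- runif(12)
  ud <- rasterGrid(matrix(v / sum(v), 3, 4), gridSpecify(3, 4, 0, 0, 1))
  iso <- isopleth(ud, 0.8)
  greedySize <- sum(iso$mask)
  ## exhaustive search over all 2^12 subsets for the smallest set with
  ## mass >= 0.8
  best <- Inf
  vals <- as.vector(ud@values)
  for (code in 1:(2^12 - 1)) {
    sel <- as.logical(intToBits(code)[1:12])
    if (sum(vals[sel]) >= 0.8) best <- min(best, sum(sel))
  }
  expect_equal(greedySize, best)
})

test_that("home ranges assemble per individual-season with the 60-day rule", {
  days <- seq(as.POSIXct("2013-04-01 12:00", tz = "UTC"), by = "day",
              length.out = 120)
  set.seed(5)
  f1 <- mkFixes(cbind(rnorm(120, 0, 1500), rnorm(120, 0, 1500)), days,
                id = "L1", sex = "F", birth = as.Date("2005-01-01"))
  f2 <- mkFixes(cbind(rnorm(30, 0, 1500), rnorm(30, 0, 1500)), days[1:30],
                id = "L2", sex = "M", birth = as.Date("2010-06-01"))
  clean <- preprocessTelemetry(rbind(f1, f2))
  uds <- homeRanges(clean, minDays = 60)
  expect_equal(names(uds), "L1.2013")  # L2 falls below the data rule
  u <- uds[[1]]
  expect_equal(u@demographicClass, "adult female")
  expect_equal(sum(u@ud@values), 1, tolerance = 1e-6)
  expect_gte(u@nFixes, 60)
})
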