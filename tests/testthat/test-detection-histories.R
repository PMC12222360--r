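test_that("replicate construction follows along-road order and arithmetic", {
  ## 12 km of road in one 8 km cell row: 6 replicates of 2 km
  g <- gridSpecify(8, 12, 0, 0, 1000)
  lam <- rasterGrid(matrix(1, 8, 12), g)
  road <- list(cbind(x = c(0, 12000), y = c(4000, 4000)))
  sv <- simulateTrackSurvey(lam, road, siteSize = 16000,
                            replicateLength = 2000,
                            truth = preyTruth("sp", r = 0.5), seed = 1)
  expect_equal(nrow(sv$records), 6)
  expect_equal(sv$records$replicate, 1:6)
  ## total replicates over a toy network = sum over sites of
  ## floor(site road length / 2 km)
  g2 <- gridSpecify(24, 24, 0, 0, 1000)
  lam2 <- rasterGrid(matrix(1, 24, 24), g2)
  roads2 <- makeRoadNetwork(g2, 8000)
  sv2 <- simulateTrackSurvey(lam2, roads2, siteSize = 8000,
                             replicateLength = 2000,
                             truth = preyTruth("sp", r = 0.5), seed = 2)
  ## 3 transects of 24 km crossing 3 site columns: 9 sites x 4 replicates
  expect_equal(nrow(sv2$records), 9 * 4)
  expect_equal(sum(sv2$sites$transectLength), 3 * 24000)
})

test_that("aggregation OR-merges blocks and drops remainders", {
  dh <- mkDH(matrix(c(1L, 0L, 0L, 1L, 0L, 0L), 1))
  dh6 <- aggregateReplicates(dh, 3)
  expect_equal(as.vector(dh6@y), c(1L, 1L))
  expect_equal(dh6@replicateLength, 6000)
  ## remainder discarded: 7 base replicates at k = 3 -> 2 aggregated
  dh7 <- mkDH(matrix(c(0L, 0L, 0L, 0L, 0L, 0L, 1L), 1))
  expect_equal(sum(!is.na(aggregateReplicates(dh7, 3)@y)), 2)
  expect_error(aggregateReplicates(dh, 2.5), "multiple")
  ## site covariates follow the retained sites
  y <- rbind(rep(0L, 6), c(1L, rep(NA, 5)))
  dh2 <- mkDH(y, data.frame(x1 = c(10, 20)))
  agg <- aggregateReplicates(dh2, 3)
  expect_equal(nrow(agg@y), 1)
  expect_equal(agg@siteCovs$x1, 10)
})

test_that("replicate-length rule tracks detection clustering", {
  g <- gridSpecify(40, 40, 0, 0, 1000)
  lam <- rasterGrid(matrix(1.5, 40, 40), g)
  roads <- makeRoadNetwork(g, 8000)
  ## strongly clustered segment presence: Markov wins at short lengths
  tClu <- preyTruth("clu", a0 = log(1.5), r = 0.9,
                    theta0 = 0.12, theta1 = 0.85)
  sv <- simulateTrackSurvey(lam, roads, siteSize = 8000,
                            replicateLength = 2000, truth = tClu, seed = 4)
  dh <- buildDetectionHistories(sv$records, replicateLength = 2000)
  sel <- suppressWarnings(selectReplicateLength(dh, maxLength = 10000))
  expect_gt(sel$chosen, 2000)
  expect_equal(nrow(sel$trace), sum(seq(2000, 10000, 2000) <= sel$chosen))
  expect_true(all(c("aiccMackenzie", "aiccMarkov") %in% names(sel$trace)))
  expect_error(selectReplicateLength(mkDH(matrix(0L, 3, 4))), "degenerate")
})
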