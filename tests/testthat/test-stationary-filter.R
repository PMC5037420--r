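# Noise density estimation and the Monte-Carlo stationary-mode filter.

test_that("fitNoiseDensity builds a max-normalized histogram over the hull", {
  fixed <- cnSeriesFromTrajectory(simulateFixedCell(0.17, 1001, seed = 1))
  dens <- suppressWarnings(fitNoiseDensity(fixed))
  expect_s4_class(dens, "NoiseDensity")
  expect_equal(max(dens@pGrid), 1)
  expect_true(all(dens@pGrid >= 0 & dens@pGrid <= 1))
  # doubling every count leaves the max-normalized grid unchanged
  p <- cnPoints(fixed)[, c("ncd_par", "ccd", "region")]
  dens2 <- fitNoiseDensity(rbind(p, p))
  expect_equal(dens2@pGrid, dens@pGrid)
  # density is maximal at small CCD and decays outward along CCD
  colMax <- apply(dens@pGrid, 2, max)
  expect_lt(mean(colMax[(length(colMax) - 4):length(colMax)]),
            mean(colMax[1:8]))
  expect_error(fitNoiseDensity(p[1, , drop = FALSE]), "at least 2")
  expect_warning(fitNoiseDensity(p[1:50, ]), "coarse")
})

test_that("noiseProbability looks up bins with the lower-bin tie-break", {
  dens <- new("NoiseDensity",
              edgesNcdPar = seq(0, 1, by = 0.25),
              edgesCcd = seq(0, 1, by = 0.25),
              pGrid = matrix(seq(0.04, 0.64, by = 0.04), 4, 4),
              nSourcePoints = 100L, normalization = "max")
  # mid-bin lookups
  expect_equal(noiseProbability(dens, 0.1, 0.1), dens@pGrid[1, 1])
  expect_equal(noiseProbability(dens, 0.6, 0.9), dens@pGrid[3, 4])
  # interior edge belongs to the lower-index bin
  expect_equal(noiseProbability(dens, 0.25, 0.1), dens@pGrid[1, 1])
  expect_equal(noiseProbability(dens, 0.26, 0.1), dens@pGrid[2, 1])
  # extreme edges are inside the hull
  expect_equal(noiseProbability(dens, 0, 0), dens@pGrid[1, 1])
  expect_equal(noiseProbability(dens, 1, 1), dens@pGrid[4, 4])
  # out of hull -> 0
  expect_equal(noiseProbability(dens, -0.1, 0.5), 0)
  expect_equal(noiseProbability(dens, 0.5, 50), 0)
})

test_that("monteCarloFilter reassigns only I-IV -> V, reproducibly", {
  s <- randomCNSeries(500, seed = 21)
  zeroDens <- new("NoiseDensity", edgesNcdPar = c(-10, 0, 10),
                  edgesCcd = c(0, 5, 10),
                  pGrid = matrix(0, 2, 2), nSourcePoints = 10L,
                  normalization = "max")
  oneDens <- zeroDens
  oneDens@pGrid <- matrix(1, 2, 2)
  oneDens@edgesNcdPar <- c(-100, 0, 100); oneDens@edgesCcd <- c(0, 50, 100)

  # density identically zero: nothing reassigned
  f0 <- monteCarloFilter(s, zeroDens, seed = 1)
  expect_identical(regionLabels(f0), regionLabels(s))
  # density identically one over the hull: everything reassigned
  f1 <- monteCarloFilter(s, oneDens, seed = 1)
  expect_true(all(regionLabels(f1) == "V"))
  expect_identical(cnPoints(f1)$region_original, regionLabels(s))
  # fixed seed: bit-identical reruns
  expect_identical(cnPoints(monteCarloFilter(s, oneDens, seed = 7)),
                   cnPoints(monteCarloFilter(s, oneDens, seed = 7)))
})

test_that("reassignment fraction matches the mean noise probability", {
  fixed <- cnSeriesFromTrajectory(simulateFixedCell(0.16, 5001, seed = 3))
  dens <- fitNoiseDensity(fixed)
  filt <- monteCarloFilter(fixed, dens, seed = 4)
  p <- cnPoints(filt)
  frac <- mean(p$region == "V")
  pbar <- mean(p$noise_p)
  se <- sqrt(sum(p$noise_p * (1 - p$noise_p))) / nrow(p)
  expect_lt(abs(frac - pbar), 3 * se)
})

test_that("five-region CMPI equals four-region CMPI when p is zero", {
  s <- randomCNSeries(200, seed = 5)
  zeroDens <- new("NoiseDensity", edgesNcdPar = c(-10, 0, 10),
                  edgesCcd = c(0, 5, 10), pGrid = matrix(0, 2, 2),
                  nSourcePoints = 10L, normalization = "max")
  filt <- monteCarloFilter(s, zeroDens, seed = 2)
  expect_equal(cmpiValue(cellCMPI(filt, scheme = "five")),
               cmpiValue(cellCMPI(s, scheme = "four")), tolerance = 1e-15)
})

test_that("prolongedStationarySegments keeps only runs strictly longer than minRun", {
  labs <- c(rep("I", 3), rep("V", 6), "II", rep("V", 5), rep("III", 2))
  seg <- prolongedStationarySegments(labs, minRun = 5)
  expect_equal(nrow(seg), 1)           # run of 6 kept, run of 5 dropped
  expect_equal(seg$start, 4)
  expect_equal(seg$end, 9)
  expect_equal(nrow(prolongedStationarySegments(rep("I", 10))), 0)
})
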