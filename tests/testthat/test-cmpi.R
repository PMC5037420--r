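# CMPI: per-cell index, population summary, running window, convergence.

test_that("cellCMPI reproduces the hand-computed example", {
  # two points in Region I (ncd_par 2, 1), two in Region III
  s <- cnmotility:::newCNSeries("hand", 1, ccd = c(1, 1, 1, 1),
                                ncdPar = c(2, 1, 0, 0))
  r <- cellCMPI(s)
  expect_equal(occurrence(r)[["I"]], 0.5)
  expect_equal(r@regionMeanNcdPar[["I"]], 1.5)
  expect_equal(cmpiValue(r), 0.75)

  # all Region III: index is zero (only Regions I and II contribute)
  s3 <- cnmotility:::newCNSeries("p", 1, ccd = rep(1, 5), ncdPar = rep(0, 5))
  expect_equal(cmpiValue(cellCMPI(s3)), 0)

  # frozen nucleus => NCD// = 0 everywhere => CMPI exactly 0
  n <- 30
  tp <- trajectoryPair("frozen", 0:n, cbind(0:n, sin(0:n)),
                       matrix(5, n + 1, 2))
  expect_equal(cmpiValue(cellCMPI(cnSeriesFromTrajectory(tp))), 0)
})

test_that("CMPI equals the direct-sum form on random series", {
  for (i in 1:25) {
    s <- randomCNSeries(80, seed = 100 + i)
    p <- cnPoints(s)
    def <- p$region != "UNDEFINED"
    direct <- sum(p$ncd_par[def & p$theta <= 75]) / sum(def)
    expect_equal(cmpiValue(cellCMPI(s)), direct, tolerance = 1e-12)
  }
})

test_that("CMPI is rigid-motion invariant and scales with the spatial unit", {
  se <- simulateEvents(mixedEventScript(50, jitterSigma = 0.05, seed = 4))
  base <- cmpiValue(cellCMPI(cnSeriesFromTrajectory(se$trajectory)))
  moved <- transformTrajectory(se$trajectory, 77, c(4, -9))
  expect_equal(cmpiValue(cellCMPI(cnSeriesFromTrajectory(moved))), base,
               tolerance = 1e-9)
  k <- 2.5
  scaled <- trajectoryPair("s", trackTimes(se$trajectory),
                           k * cellTrack(se$trajectory),
                           k * nucTrack(se$trajectory))
  expect_equal(cmpiValue(cellCMPI(cnSeriesFromTrajectory(scaled))), k * base,
               tolerance = 1e-9)
})

test_that("a higher detachment rate raises expected CMPI", {
  mkPool <- function(detachFrac, seeds) {
    vapply(seeds, function(sd) {
      set.seed(sd)
      ev <- sample(c("detachment", "protrusion"), 60, TRUE,
                   prob = c(detachFrac, 1 - detachFrac))
      se <- simulateEvents(eventScript(ev, jitterSigma = 0.02, seed = sd))
      cmpiValue(cellCMPI(cnSeriesFromTrajectory(se$trajectory)))
    }, numeric(1))
  }
  lo <- mkPool(0.2, 1:20)
  hi <- mkPool(0.6, 1:20)
  expect_gt(mean(hi), mean(lo))
  expect_lt(stats::t.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("populationCMPI returns mean, SEM and n", {
  expect_equal(populationCMPI(c(1, 3)), c(mean = 2, sem = 1, n = 2))
  expect_equal(populationCMPI(rep(2.5, 10))[["sem"]], 0)
  expect_error(populationCMPI(5), "at least 2")
  # SEM shrinks as 1/sqrt(n) on i.i.d. cells
  set.seed(6)
  v <- rnorm(400, 1, 0.3)
  s50 <- populationCMPI(v[1:50])[["sem"]]
  s200 <- populationCMPI(v[1:200])[["sem"]]
  expect_equal(s200 / s50, 0.5, tolerance = 0.25)
})

test_that("runningCMPI windows behave at the identities", {
  s <- randomCNSeries(60, seed = 12)
  whole <- cmpiValue(cellCMPI(s))
  full <- runningCMPI(s, 60)
  expect_equal(nrow(full), 1)
  expect_equal(full$cmpi, whole, tolerance = 1e-12)

  # constant-region, constant-ncd_par series: constant running values
  sc <- cnmotility:::newCNSeries("c", 1, ccd = rep(1, 30), ncdPar = rep(1.4, 30))
  rc <- runningCMPI(sc, 10)
  expect_equal(rc$cmpi, rep(1.4, 21))

  # detachment phase then protrusion phase: earlier windows score higher
  se <- simulateEvents(eventScript(c(rep("detachment", 30),
                                     rep("protrusion", 30)),
                                   jitterSigma = 0.01, seed = 2))
  rr <- runningCMPI(cnSeriesFromTrajectory(se$trajectory), 10)
  expect_gt(rr$cmpi[1], rr$cmpi[nrow(rr)])
  expect_error(runningCMPI(s, 61), "window")
})

test_that("convergenceCurve is deterministic and flags identical pools at once", {
  pool <- rep(2, 30)
  cc <- convergenceCurve(pool, step = 5, nIterations = 20, seed = 3)
  expect_equal(cc$sem, rep(0, 6))
  expect_equal(attr(cc, "converged_at"), 5)
  # fixed seed => identical table
  pool2 <- rnorm(50, 1, 0.35)
  a <- convergenceCurve(pool2, 5, 50, seed = 9)
  b <- convergenceCurve(pool2, 5, 50, seed = 9)
  expect_identical(a, b)
  expect_error(convergenceCurve(rnorm(3), step = 5), "smaller than the step")
})
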