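# Core geometry: displacement pairs, projection, angular classification.

test_that("displacementPairs returns stride-1 consecutive differences", {
  tp <- trajectoryPair("c", 0:3, cbind(c(0, 1, 3, 6), 0),
                       cbind(c(0, 0.5, 1, 1.5), 0))
  dp <- displacementPairs(tp, 1)
  expect_equal(dp$cell[, 1], c(1, 2, 3))
  expect_equal(dp$nuc[, 1], c(0.5, 0.5, 0.5))

  # a one-hour movie at 1-min spacing gives 60 correlation points
  tp61 <- trajectoryPair("c", 0:60, cbind(0:60, 0), cbind(0:60, 0))
  expect_equal(nrow(displacementPairs(tp61, 1)$cell), 60)
  expect_equal(nrow(displacementPairs(tp61, 3)$cell), 58)
  expect_error(displacementPairs(tp61, 61), "smaller than the track length")
})

test_that("projectNCD computes signed projections and degenerate cases", {
  expect_equal(projectNCD(c(1, 0), c(0.5, 0.7))$ncdPar, 0.5)
  expect_equal(projectNCD(c(3, 4), c(3, 4)),
               list(ccd = 5, ncdPar = 5, degenerate = FALSE))
  # orthogonal nucleus motion projects to zero
  expect_equal(projectNCD(c(1, 0), c(0, 2))$ncdPar, 0)
  # opposite direction is negative
  expect_lt(projectNCD(c(1, 0), c(-1, 0.2))$ncdPar, 0)
  # zero CCD: degenerate, |NCD| reported
  d <- projectNCD(c(0, 0), c(3, 4))
  expect_true(d$degenerate)
  expect_equal(d$ncdPar, 5)
  expect_error(projectNCD(c(1, NA), c(0, 0)), "finite")
})

test_that("classifyRegion follows the half-open angular brackets", {
  # boundary angles belong to the lower-numbered region
  expect_equal(classifyRegion(1, 1), "I")               # theta = 45
  expect_equal(classifyRegion(1, 0), "III")             # theta = 90
  expect_equal(classifyRegion(0.2, -1), "IV")           # theta ~ 168.7
  # probes just inside each bracket
  th <- function(deg) classifyRegion(sin(deg * pi / 180), cos(deg * pi / 180))
  expect_equal(th(c(10, 44.99, 46, 74.99, 76, 104.99, 106, 179)),
               c("I", "I", "II", "II", "III", "III", "IV", "IV"))
  expect_equal(classifyRegion(0, 5), "UNDEFINED")
  expect_error(classifyRegion(-1, 0), "non-negative")
})

test_that("every defined point gets exactly one region, matching the oracle", {
  set.seed(42)
  n <- 2000
  ccd <- abs(rnorm(n)) * rbinom(n, 1, 0.98)  # some exact zeros
  ncdPar <- rnorm(n)
  got <- classifyRegion(ccd, ncdPar)
  expect_equal(got, unname(bruteRegion(ccd, ncdPar)))
  expect_true(all(got[ccd > 1e-12] %in% c("I", "II", "III", "IV")))
  expect_true(all(got[ccd <= 1e-12] == "UNDEFINED"))
})

test_that("cnSeriesFromTrajectory composes the pipeline in interval order", {
  # straight co-moving tracks: cell 1 um/step, nucleus 1.5 um/step
  n <- 20
  tp <- trajectoryPair("co", 0:n, cbind(0:n, 0), cbind(1.5 * (0:n), 0))
  s <- cnSeriesFromTrajectory(tp)
  expect_s4_class(s, "CNSeries")
  p <- cnPoints(s)
  expect_equal(nrow(p), n)
  expect_true(all(p$region == "I"))
  expect_equal(p$theta, rep(atan2(1, 1.5) * 180 / pi, n))

  # frozen nucleus: NCD// = 0 everywhere, theta = 90
  tp2 <- trajectoryPair("frozen", 0:n,
                        cbind(cumsum(c(0, runif(n, 0.5, 1))),
                              cumsum(c(0, runif(n, -1, 1)))),
                        matrix(2, n + 1, 2))
  p2 <- cnPoints(cnSeriesFromTrajectory(tp2))
  expect_equal(p2$ncd_par, rep(0, n))
  expect_true(all(p2$region == "III"))
})

test_that("CN series are rotation/translation invariant and scale equivariant", {
  se <- simulateEvents(mixedEventScript(40, jitterSigma = 0.05, seed = 3))
  base <- cnPoints(cnSeriesFromTrajectory(se$trajectory))
  for (deg in c(30, 119.5, 270)) {
    moved <- transformTrajectory(se$trajectory, deg, c(-12.3, 7.7))
    p <- cnPoints(cnSeriesFromTrajectory(moved))
    expect_equal(p$ccd, base$ccd, tolerance = 1e-9)
    expect_equal(p$ncd_par, base$ncd_par, tolerance = 1e-9)
    expect_equal(p$region, base$region)
  }
  # pure translation is exact
  shifted <- transformTrajectory(se$trajectory, 0, c(1e3, -1e3))
  expect_identical(cnPoints(cnSeriesFromTrajectory(shifted))$region,
                   base$region)
  # scaling by s scales ccd and ncd_par, leaves theta/regions unchanged
  s <- 3.7
  scaled <- trajectoryPair("sc", trackTimes(se$trajectory),
                           s * cellTrack(se$trajectory),
                           s * nucTrack(se$trajectory))
  ps <- cnPoints(cnSeriesFromTrajectory(scaled))
  expect_equal(ps$ccd, s * base$ccd, tolerance = 1e-12)
  expect_equal(ps$ncd_par, s * base$ncd_par, tolerance = 1e-12)
  expect_equal(ps$region, base$region)
})

test_that("seriesAutocorrelation matches its closed-form cases", {
  expect_equal(seriesAutocorrelation(rep(3.2, 50), 5), rep(1, 6))
  alt <- rep(c(1, -1), 50)
  r <- seriesAutocorrelation(alt, 2)
  expect_equal(r[1], 1)
  expect_equal(r[2], -0.99, tolerance = 0.011)   # -(n-1)/n
  set.seed(9)
  riid <- seriesAutocorrelation(rnorm(1000), 1)
  expect_lt(abs(riid[2]), 3 / sqrt(1000))
  # NA (UNDEFINED) entries are excluded pairwise, not fatal
  x <- rnorm(100); x[c(10, 50)] <- NA
  expect_length(seriesAutocorrelation(x, 3), 4)
  expect_error(seriesAutocorrelation(1:4, 5), "too short")
})
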