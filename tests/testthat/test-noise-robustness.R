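# Noise injection, noise-implemented CMPI and the tau x sigma grid.

test_that("estimateIntrinsicSigma recovers anisotropic jitter per axis", {
  set.seed(33)
  T <- 600
  tp <- trajectoryPair("aniso", 0:(T - 1),
                       cbind(rnorm(T, 0, 0.3), rnorm(T, 0, 0.1)),
                       matrix(0.5, T, 2))
  est <- estimateIntrinsicSigma(tp)
  expect_equal(est[["sigma_x"]], 0.3, tolerance = 0.1)
  expect_equal(est[["sigma_y"]], 0.1, tolerance = 0.1)
  # zero-jitter track gives exactly (0, 0) on the nucleus channel
  expect_equal(unname(estimateIntrinsicSigma(tp, "nucleus")), c(0, 0))
  short <- trajectoryPair("s", 0:9, matrix(rnorm(20), 10, 2),
                          matrix(0, 10, 2))
  expect_error(estimateIntrinsicSigma(short), "at least 30")
})

test_that("injectDisplacementNoise is the identity at sigma 0 and seeded", {
  pairs <- randomPairs(50, seed = 3)
  expect_identical(injectDisplacementNoise(pairs, 0, seed = 1)$cell,
                   pairs$cell)
  a <- injectDisplacementNoise(pairs, 0.5, seed = 4)
  b <- injectDisplacementNoise(pairs, 0.5, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$cell, pairs$cell))
  expect_error(injectDisplacementNoise(pairs, -0.1), "non-negative")
})

test_that("overwhelming noise drives regions to the isotropic distribution", {
  # tiny true displacements swamped by sigma = 10 um: (NCD//, CCD) becomes
  # (Gaussian projection, independent Rayleigh), i.e. theta is the polar
  # angle of a 3-D isotropic Gaussian with density sin(theta)/2, so the
  # region fraction over [t1, t2] is (cos t1 - cos t2) / 2
  se <- simulateEvents(eventScript(rep("detachment", 4000),
                                   cellStep = 0.01))
  pairs <- displacementPairs(se$trajectory)
  noisy <- injectDisplacementNoise(pairs, 10, seed = 6)
  pr <- projectNCD(noisy$cell, noisy$nuc)
  occ <- regionOccurrence(classifyRegion(pr$ccd, pr$ncdPar))
  cosd <- function(d) cos(d * pi / 180)
  ref <- diff(-cosd(c(0, 45, 75, 105, 180))) / 2
  expect_equal(unname(occ), ref, tolerance = 0.1)
})

test_that("noiseImplementedCMPI reproduces the noise-free value at sigma 0", {
  cells <- lapply(1:5, function(i)
    simulateEvents(mixedEventScript(40, jitterSigma = 0.02,
                                    seed = i))$trajectory)
  ref <- mean(vapply(cells, function(tp)
    cmpiValue(cellCMPI(cnSeriesFromTrajectory(tp))), numeric(1)))
  sw <- noiseImplementedCMPI(cells, sigmas = 0, repeats = 3, seed = 2)
  expect_identical(sw@meanCMPI, ref)
  # deterministic under a fixed seed
  sw2 <- noiseImplementedCMPI(cells, sigmas = c(0.1, 0.5), repeats = 5,
                              seed = 11)
  sw3 <- noiseImplementedCMPI(cells, sigmas = c(0.1, 0.5), repeats = 5,
                              seed = 11)
  expect_identical(sw2@meanCMPI, sw3@meanCMPI)
  expect_error(noiseImplementedCMPI(cells, numeric(0)), "non-empty")
})

test_that("repeat averaging shrinks the spread of the sweep estimate", {
  cells <- lapply(1:4, function(i)
    simulateEvents(mixedEventScript(30, jitterSigma = 0.02,
                                    seed = i))$trajectory)
  est <- function(repeats, seeds) vapply(seeds, function(sd)
    noiseImplementedCMPI(cells, 0.5, repeats = repeats, seed = sd)@meanCMPI,
    numeric(1))
  v1 <- var(est(1, 1:12))
  v16 <- var(est(16, 1:12))
  expect_lt(v16, v1)
  # and the two agree in expectation
  expect_lt(abs(mean(est(16, 1:12)) - mean(est(1, 1:12))),
            3 * sqrt(v1 / 12))
})

test_that("robustnessGrid returns perfect linearity for proportional types", {
  # six noise-free detachment-only types: CMPI is proportional to the
  # step size, so pairing them with mu = step gives R^2 = 1 at every tau
  steps <- c(0.2, 0.5, 0.8, 1.1, 1.5, 2.0)
  types <- lapply(steps, function(s) list(
    simulateEvents(eventScript(rep("detachment", 60),
                               cellStep = s))$trajectory))
  names(types) <- paste0("t", seq_along(steps))
  mu <- steps; names(mu) <- names(types)
  grid <- robustnessGrid(types, mu, taus = c(1, 2, 3), sigmas = 0,
                         repeats = 1, seed = 1)
  expect_true(all(grid$r_squared > 0.999999))
  expect_error(robustnessGrid(types[1:2], mu[1:2]), "at least 3")
  # subsampling to tau = 2 equals re-reading every other frame
  tp <- types[[1]][[1]]
  sub <- subsampleTrajectory(tp, 2)
  expect_identical(cellTrack(sub),
                   cellTrack(tp)[seq(1, 61, by = 2), ])
  expect_equal(samplingTau(sub), 2)
})
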