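# Fixture builders and independent oracles shared across test files.

# Random displacement pairs (cell + nucleus vectors).
randomPairs <- function(n, seed) {
  set.seed(seed)
  list(cell = matrix(rnorm(2 * n), n, 2), nuc = matrix(rnorm(2 * n), n, 2))
}

# Random CNSeries built from raw (ccd, ncd_par) draws.
randomCNSeries <- function(n, seed, cellId = "rand") {
  set.seed(seed)
  cnmotility:::newCNSeries(cellId, tau = 1,
                           ccd = abs(rnorm(n)) + 1e-6,
                           ncdPar = rnorm(n))
}

# Brute-force region oracle: angle between the (NCD//, CCD) point and the
# NCD// axis via explicit arccos with sign handling (independent of the
# atan2 path used by classifyRegion).
bruteRegion <- function(ccd, ncdPar) {
  mapply(function(c, np) {
    if (c <= 1e-12) return("UNDEFINED")
    r <- sqrt(c^2 + np^2)
    th <- acos(np / r) * 180 / pi       # in [0, 180] since ccd > 0
    if (th <= 45) "I"
    else if (th <= 75) "II"
    else if (th <= 105) "III"
    else "IV"
  }, ccd, ncdPar)
}

# Rotate a T x 2 matrix by `deg` degrees about the origin.
rotate2d <- function(m, deg) {
  r <- deg * pi / 180
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  m %*% t(R)
}

# Apply one rigid motion (rotation + translation) to both tracks.
transformTrajectory <- function(traj, deg = 0, offset = c(0, 0)) {
  trajectoryPair(cellId(traj), trackTimes(traj),
                 sweep(rotate2d(cellTrack(traj), deg), 2, offset, "+"),
                 sweep(rotate2d(nucTrack(traj), deg), 2, offset, "+"))
}

# A mixed-event script cycling through all activity types.
mixedEventScript <- function(n = 60, jitterSigma = 0.02, seed = 1,
                             cellStep = 1) {
  events <- rep(c("detachment", "protrusion", "mixed", "turn",
                  "detachment", "stationary"), length.out = n)
  eventScript(events, cellStep = cellStep, jitterSigma = jitterSigma,
              seed = seed)
}
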