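# Synthetic-data generators: event-scripted cell/nucleus kinematics with
# ground-truth labels, exact Ornstein-Uhlenbeck persistent random walks,
# and fixed-cell positional jitter.

#' Construct an event script
#'
#' @param events character vector of per-interval event labels from
#'   \code{protrusion, retraction, detachment, mixed, turn, stationary}.
#' @param cellStep cell centroid step per interval (um), recycled.
#' @param detachRatio nucleus/cell step ratio during detachment (> 1;
#'   default 1.5 — the nucleus, having the smaller footprint, translates
#'   further than the whole-cell centroid when the trailing edge releases).
#' @param mixedFraction nucleus/cell step ratio during mixed events
#'   (default 0.5, landing in Region II).
#' @param turnAngle heading change of a turn, degrees in (90, 180]
#'   (default 135).
#' @param turnNucFraction nucleus step during a turn as a fraction of the
#'   cell step, taken in the pre-turn heading (default 0.5; the nucleus
#'   retains its inertia).
#' @param direction0 initial heading, degrees (default 0).
#' @param jitterSigma per-axis Gaussian positional jitter sd (um,
#'   default 0).
#' @param tau minutes per interval (default 1).
#' @param seed integer RNG seed for the jitter.
#' @return An \linkS4class{EventScript}.
#' @export
eventScript <- function(events, cellStep = 1, detachRatio = 1.5,
                        mixedFraction = 0.5, turnAngle = 135,
                        turnNucFraction = 0.5, direction0 = 0,
                        jitterSigma = 0, tau = 1, seed = 1L) {
  new("EventScript", events = as.character(events),
      cellStep = as.numeric(cellStep), detachRatio = detachRatio,
      mixedFraction = mixedFraction, turnAngle = turnAngle,
      turnNucFraction = turnNucFraction, direction0 = direction0,
      jitterSigma = jitterSigma, tau = tau, seed = as.integer(seed))
}

#' Simulate a cell-nucleus trajectory pair from an event script
#'
#' Deterministic kinematics per event (see \linkS4class{EventScript}) plus
#' seeded isotropic Gaussian jitter on both tracks. Without jitter, a
#' protrusion interval produces NCD// = 0 (Region III), a detachment
#' interval NCD// = detachRatio x CCD (Region I for the default ratio 1.5,
#' theta = atan2(1, 1.5) ~ 33.7 deg), and a turn a negative NCD//
#' (Region IV for the defaults).
#'
#' @param script an \linkS4class{EventScript}.
#' @param cellId identifier for the generated cell (default "sim").
#' @return List with elements \code{trajectory}
#'   (\linkS4class{TrajectoryPair}) and \code{labels} (the ground-truth
#'   event of each interval).
#' @export
simulateEvents <- function(script, cellId = "sim") {
  stopifnot(is(script, "EventScript"))
  ev <- script@events
  n <- length(ev)
  if (n < 1L) stop("the script must contain at least one event")
  steps <- rep_len(script@cellStep, n)
  cellXY <- matrix(0, n + 1L, 2L)
  nucXY <- matrix(0, n + 1L, 2L)
  phi <- script@direction0
  for (i in seq_len(n)) {
    s <- steps[i]
    dc <- c(0, 0); dn <- c(0, 0)
    switch(ev[i],
      protrusion = { dc <- s * unitVec(phi) },
      retraction = { dc <- s * unitVec(phi + 180) },
      detachment = { dc <- s * unitVec(phi)
                     dn <- script@detachRatio * s * unitVec(phi) },
      mixed      = { dc <- s * unitVec(phi)
                     dn <- script@mixedFraction * s * unitVec(phi) },
      turn       = { newPhi <- phi + script@turnAngle
                     dc <- s * unitVec(newPhi)
                     dn <- script@turnNucFraction * s * unitVec(phi)
                     phi <- newPhi },
      stationary = { })
    cellXY[i + 1L, ] <- cellXY[i, ] + dc
    nucXY[i + 1L, ] <- nucXY[i, ] + dn
  }
  if (script@jitterSigma > 0) {
    jit <- withSeed(script@seed,
                    matrix(stats::rnorm(4L * (n + 1L), 0, script@jitterSigma),
                           n + 1L, 4L))
    cellXY <- cellXY + jit[, 1:2]
    nucXY <- nucXY + jit[, 3:4]
  }
  traj <- trajectoryPair(cellId, seq(0, by = script@tau, length.out = n + 1L),
                         cellXY, nucXY)
  list(trajectory = traj, labels = ev)
}

#' Simulate exact Ornstein-Uhlenbeck persistent-random-walk tracks
#'
#' The velocity of each coordinate follows an OU process with relaxation
#' time P and stationary per-component variance S^2/2 (so the 2-D
#' root-mean-square speed is S); positions are advanced by sampling the
#' exact joint Gaussian transition of the integrated OU process, so the
#' ensemble MSD equals the Fuerth form 2 S^2 P [t - P(1 - exp(-t/P))]
#' without discretization bias at any step size.
#'
#' @param S root-mean-square speed (um/min).
#' @param P persistence time (minutes).
#' @param tau sampling interval (minutes).
#' @param nSteps number of steps (tracks have nSteps + 1 frames).
#' @param nTracks number of independent tracks.
#' @param seed integer RNG seed.
#' @return List of nTracks (nSteps + 1) x 2 position matrices (um), with
#'   attributes \code{times}, \code{S}, \code{P}, \code{tau}, \code{seed}.
#' @export
simulatePRW <- function(S = 1, P = 10, tau = 1, nSteps = 60L, nTracks = 1L,
                        seed = 1L) {
  stopifnot(S > 0, P > 0, tau > 0, nSteps >= 1L, nTracks >= 1L)
  nSteps <- as.integer(nSteps); nTracks <- as.integer(nTracks)
  a <- exp(-tau / P)
  sv2 <- S^2 / 2                      # stationary velocity variance per axis
  Vv <- sv2 * (1 - a^2)               # Var(v_{k+1} | v_k)
  Vx <- sv2 * P^2 * (2 * tau / P - 3 + 4 * a - a^2)  # Var(dx | v_k)
  Cxv <- sv2 * P * (1 - a)^2          # Cov(dx, v_{k+1} | v_k)
  condVar <- max(Vx - Cxv^2 / Vv, 0)  # Var(dx | v_k, v_{k+1})
  m <- nTracks * 2L                   # both coordinates simulated jointly
  withSeed(seed, {
    v <- matrix(stats::rnorm(m, 0, sqrt(sv2)), nTracks, 2L)
    x <- array(0, dim = c(nSteps + 1L, nTracks, 2L))
    for (k in seq_len(nSteps)) {
      vNew <- a * v + matrix(stats::rnorm(m, 0, sqrt(Vv)), nTracks, 2L)
      dx <- v * P * (1 - a) + (Cxv / Vv) * (vNew - a * v) +
        matrix(stats::rnorm(m, 0, sqrt(condVar)), nTracks, 2L)
      x[k + 1L, , ] <- x[k, , ] + dx
      v <- vNew
    }
    tracks <- lapply(seq_len(nTracks), function(i) x[, i, ])
    attr(tracks, "times") <- seq(0, by = tau, length.out = nSteps + 1L)
    attr(tracks, "S") <- S; attr(tracks, "P") <- P
    attr(tracks, "tau") <- tau; attr(tracks, "seed") <- as.integer(seed)
    tracks
  })
}

#' Ensemble MSD over many tracks
#'
#' Overlapping MSD pooled over all start points of all tracks — the
#' estimator used when validating the simulator against the closed-form
#' Fuerth MSD.
#'
#' @param tracks list of T x 2 position matrices sharing a time grid (as
#'   returned by \code{\link{simulatePRW}}).
#' @param tau sampling interval (minutes); defaults to the tracks'
#'   attribute when present.
#' @param maxLagFraction largest lag as a fraction of T - 1.
#' @return An \linkS4class{MSDCurve}.
#' @export
ensembleMSD <- function(tracks, tau = attr(tracks, "tau"),
                        maxLagFraction = 0.25) {
  if (is.null(tau)) tau <- 1
  xs <- simplify2array(tracks)         # T x 2 x n
  T <- dim(xs)[1L]
  n <- dim(xs)[3L]
  if (T < 8L) stop("tracks too short for MSD (need at least 8 frames)")
  maxK <- max(1L, floor(maxLagFraction * (T - 1L)))
  msd <- numeric(maxK); nPairs <- integer(maxK)
  for (k in seq_len(maxK)) {
    d1 <- xs[(k + 1L):T, 1L, ] - xs[1L:(T - k), 1L, ]
    d2 <- xs[(k + 1L):T, 2L, ] - xs[1L:(T - k), 2L, ]
    msd[k] <- mean(d1^2 + d2^2)
    nPairs[k] <- (T - k) * n
  }
  new("MSDCurve", lags = seq_len(maxK) * tau, msd = msd, nPairs = nPairs,
      overlapping = TRUE)
}

#' Simulate a fixed (immobile) cell with positional jitter
#'
#' Both centroids sit at a constant point plus i.i.d. per-frame Gaussian
#' jitter (per-axis sd = sigma), independent between cell and nucleus —
#' the calibration input for \code{\link{fitNoiseDensity}} and
#' \code{\link{estimateIntrinsicSigma}}.
#'
#' @param sigma per-axis jitter sd (um); typical microscope intrinsic
#'   error is ~0.16-0.17 um.
#' @param nFrames number of frames (>= 2).
#' @param tau minutes per frame.
#' @param seed integer RNG seed.
#' @param cellId identifier (default "fixed").
#' @param center length-2 numeric, the true centroid position.
#' @return A \linkS4class{TrajectoryPair}.
#' @export
simulateFixedCell <- function(sigma = 0.17, nFrames = 61L, tau = 1,
                              seed = 1L, cellId = "fixed",
                              center = c(0, 0)) {
  stopifnot(sigma >= 0, nFrames >= 2L)
  nFrames <- as.integer(nFrames)
  jit <- withSeed(seed,
                  matrix(stats::rnorm(4L * nFrames, 0, sigma), nFrames, 4L))
  trajectoryPair(cellId, seq(0, by = tau, length.out = nFrames),
                 cbind(center[1L] + jit[, 1L], center[2L] + jit[, 2L]),
                 cbind(center[1L] + jit[, 3L], center[2L] + jit[, 4L]))
}
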