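# Persistent-random-walk analysis: MSD curves, Fuerth-model fitting via
# Levenberg-Marquardt, log-log slope diagnostics, instantaneous speeds.

#' Fuerth persistent-random-walk MSD
#'
#' msd(t) = 2 S^2 P [t - P (1 - exp(-t/P))]: ballistic (~ S^2 t^2) for
#' t << P, diffusive (~ 2 S^2 P t) for t >> P.
#'
#' @param t time lags (minutes).
#' @param S root-mean-square speed (um/min).
#' @param P persistence time (minutes).
#' @return MSD in um^2.
#' @export
furthMSD <- function(t, S, P) 2 * S^2 * P * (t - P * (1 - exp(-t / P)))

#' Mean-squared displacement of a track
#'
#' For each lag k*tau up to \code{maxLagFraction} of the track duration,
#' the mean of |x(t + k tau) - x(t)|^2 over start points — all of them
#' (overlapping, the default) or strided by k (non-overlapping).
#'
#' @param positions T x 2 matrix of positions (um), or a
#'   \linkS4class{TrajectoryPair} with \code{which} selecting the track.
#' @param tau sampling interval (minutes); taken from the trajectory when
#'   one is supplied.
#' @param overlapping logical (default TRUE).
#' @param maxLagFraction largest lag as a fraction of T - 1 (default 0.25;
#'   longer lags are noise-dominated).
#' @param which \code{"cell"} or \code{"nucleus"} when \code{positions} is
#'   a TrajectoryPair.
#' @return An \linkS4class{MSDCurve}.
#' @export
computeMSD <- function(positions, tau = 1, overlapping = TRUE,
                       maxLagFraction = 0.25, which = c("nucleus", "cell")) {
  if (is(positions, "TrajectoryPair")) {
    which <- match.arg(which)
    tau <- samplingTau(positions)
    positions <- if (which == "cell") positions@cellXY else positions@nucXY
  }
  positions <- as.matrix(positions)
  T <- nrow(positions)
  if (T < 8L) stop("track too short for MSD (need at least 8 frames)")
  maxK <- max(1L, floor(maxLagFraction * (T - 1L)))
  lags <- seq_len(maxK) * tau
  msd <- numeric(maxK)
  nPairs <- integer(maxK)
  for (k in seq_len(maxK)) {
    starts <- if (overlapping) seq_len(T - k) else seq(1L, T - k, by = k)
    d <- positions[starts + k, , drop = FALSE] -
         positions[starts, , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    nPairs[k] <- length(starts)
  }
  new("MSDCurve", lags = lags, msd = msd, nPairs = nPairs,
      overlapping = isTRUE(overlapping))
}

#' Average MSD curves across tracks
#'
#' Pools the per-track curves of one cell type into a single ensemble
#' curve, weighting each track's value at a lag by its number of
#' displacement pairs. Curves must share tau; the common lag range is used.
#'
#' @param curves list of \linkS4class{MSDCurve} objects.
#' @return An \linkS4class{MSDCurve}.
#' @export
averageMSD <- function(curves) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, is, TRUE, "MSDCurve")))
  if (length(curves) == 1L) return(curves[[1L]])
  tau0 <- curves[[1L]]@lags[1L]
  if (any(abs(vapply(curves, function(c) c@lags[1L], numeric(1)) - tau0) >
          1e-9 * tau0))
    stop("curves have different lag spacing")
  nl <- min(vapply(curves, function(c) length(c@lags), integer(1)))
  w <- sapply(curves, function(c) c@nPairs[seq_len(nl)])
  m <- sapply(curves, function(c) c@msd[seq_len(nl)])
  new("MSDCurve", lags = curves[[1L]]@lags[seq_len(nl)],
      msd = rowSums(m * w) / rowSums(w),
      nPairs = as.integer(rowSums(w)),
      overlapping = curves[[1L]]@overlapping)
}

#' Fit the persistent-random-walk model to an MSD curve
#'
#' Levenberg-Marquardt least squares of the Fuerth equation
#' msd(t) = 2 S^2 P [t - P (1 - exp(-t/P))] in (S, P). Initial values:
#' S0 = sqrt(msd at the first lag) / lag (the short-lag ballistic speed),
#' P0 = 5 x the lag spacing. The diffusion coefficient is derived as
#' mu = S^2 P / 2 (2-D). Optimizer failure or non-positive estimates yield
#' a non-converged result with a diagnostic message, never a silent NaN; a
#' fitted P beyond the fitted lag range is flagged as near-ballistic
#' (the persistence time is then a lower-bound extrapolation).
#'
#' @param msdCurve an \linkS4class{MSDCurve} with at least 5 lags.
#' @param weights \code{"none"} (default, unweighted) or \code{"npairs"}
#'   (weight each lag by its number of displacement pairs).
#' @return A \linkS4class{PRWFit}.
#' @examples
#' lags <- 1:30
#' curve <- new("MSDCurve", lags = as.numeric(lags),
#'              msd = furthMSD(lags, S = 1, P = 10),
#'              nPairs = rep(100L, 30), overlapping = TRUE)
#' fitPRW(curve)
#' @export
fitPRW <- function(msdCurve, weights = c("none", "npairs")) {
  stopifnot(is(msdCurve, "MSDCurve"))
  weights <- match.arg(weights)
  t <- msdCurve@lags
  y <- msdCurve@msd
  if (length(t) < 5L) stop("need at least 5 lags to fit the PRW model")
  tau <- t[1L]
  start <- list(S = max(sqrt(y[1L]) / tau, 1e-6), P = 5 * tau)
  w <- if (weights == "npairs") as.numeric(msdCurve@nPairs)
       else rep(1, length(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ furthMSD(t, S, P),
                      start = start, weights = w,
                      lower = c(S = 1e-12, P = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new("PRWFit", S = NA_real_, P = NA_real_, mu = NA_real_,
               nDim = 2L, residualNorm = NA_real_, converged = FALSE,
               message = conditionMessage(fit)))
  est <- stats::coef(fit)
  S <- unname(est["S"]); P <- unname(est["P"])
  conv <- isTRUE(fit$convInfo$isConv) && S > 0 && P > 0
  msg <- if (!conv) "optimizer did not converge or estimates non-positive"
         else if (P > max(t))
           "near-ballistic: persistence time exceeds the fitted lag range"
         else "converged"
  new("PRWFit", S = S, P = P, mu = S^2 * P / 2, nDim = 2L,
      residualNorm = sum(stats::residuals(fit)^2),
      converged = conv, message = msg)
}

#' Log-log slope of an MSD curve
#'
#' Least-squares slope of log(msd) against log(lag): 2 for ballistic
#' motion, 1 for pure diffusion, below 1 for sub-diffusive (stationary)
#' objects — the standard motility readout of an MSD plot.
#'
#' @param msdCurve an \linkS4class{MSDCurve}.
#' @param lagRange optional c(min, max) lag window (minutes, inclusive).
#' @return Numeric slope.
#' @export
loglogSlope <- function(msdCurve, lagRange = NULL) {
  stopifnot(is(msdCurve, "MSDCurve"))
  t <- msdCurve@lags
  y <- msdCurve@msd
  if (!is.null(lagRange)) {
    keep <- t >= lagRange[1L] & t <= lagRange[2L]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 3L) stop("need at least 3 lags in the range")
  if (any(y <= 0)) stop("msd must be positive over the lag range")
  unname(stats::coef(stats::lm(log(y) ~ log(t)))[2L])
}

#' Instantaneous speeds along a track
#'
#' Per-interval speed |x(t + tau) - x(t)| / tau; on the cell track this is
#' CCD / tau for the same intervals the CN series uses.
#'
#' @param traj a \linkS4class{TrajectoryPair} (or T x 2 position matrix
#'   with \code{tau} supplied).
#' @param which \code{"cell"} or \code{"nucleus"}.
#' @param tau sampling interval (minutes) for matrix input.
#' @return Numeric vector of speeds (um/min), one per interval.
#' @export
instantaneousSpeed <- function(traj, which = c("cell", "nucleus"), tau = 1) {
  if (is(traj, "TrajectoryPair")) {
    which <- match.arg(which)
    tau <- samplingTau(traj)
    pos <- if (which == "cell") traj@cellXY else traj@nucXY
  } else pos <- as.matrix(traj)
  d <- diff(pos)
  sqrt(rowSums(d^2)) / tau
}
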