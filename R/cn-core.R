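# Core CN-correlation geometry: displacement pairs, projection, angular
# classification, and autocorrelation diagnostics.

#' Paired cell and nucleus displacement vectors
#'
#' Consecutive (stride-1, overlapping) displacement vectors of the cell and
#' nucleus centroids over \code{lagSteps} frames: pair k is
#' (cell[k+lag] - cell[k], nuc[k+lag] - nuc[k]). A track of T frames yields
#' T - lagSteps pairs; a 61-frame one-hour movie at 1-min spacing gives the
#' 60 per-minute correlation points the barcode displays.
#'
#' @param traj a \linkS4class{TrajectoryPair}.
#' @param lagSteps positive integer, number of frames per interval.
#' @return List with T - lagSteps x 2 matrices \code{cell} and \code{nuc}
#'   of displacement vectors (um).
#' @export
displacementPairs <- function(traj, lagSteps = 1L) {
  stopifnot(is(traj, "TrajectoryPair"))
  lagSteps <- as.integer(lagSteps)
  T <- length(traj@times)
  if (lagSteps < 1L) stop("lagSteps must be a positive integer")
  if (lagSteps >= T)
    stop("lagSteps (", lagSteps, ") must be smaller than the track length (",
         T, ")")
  hi <- (lagSteps + 1L):T
  lo <- 1L:(T - lagSteps)
  list(cell = traj@cellXY[hi, , drop = FALSE] - traj@cellXY[lo, , drop = FALSE],
       nuc  = traj@nucXY[hi, , drop = FALSE] - traj@nucXY[lo, , drop = FALSE])
}

#' Project the nucleus displacement onto the cell displacement direction
#'
#' CCD is the magnitude of the cell centroid displacement; NCD// is the
#' signed scalar projection of the nucleus centroid displacement onto the
#' CCD direction. When CCD is zero the direction is undefined: the
#' magnitude of the nucleus displacement is reported and the interval is
#' flagged degenerate (classified UNDEFINED downstream).
#'
#' @param ccdVec,ncdVec length-2 numeric vectors, or n x 2 matrices of
#'   displacement vectors (um).
#' @return List with numeric vectors \code{ccd}, \code{ncdPar} and logical
#'   \code{degenerate}.
#' @examples
#' projectNCD(c(3, 4), c(3, 4))   # ccd 5, ncdPar 5
#' @export
projectNCD <- function(ccdVec, ncdVec) {
  if (is.null(dim(ccdVec))) ccdVec <- matrix(ccdVec, ncol = 2)
  if (is.null(dim(ncdVec))) ncdVec <- matrix(ncdVec, ncol = 2)
  if (!all(is.finite(ccdVec)) || !all(is.finite(ncdVec)))
    stop("displacement vectors must be finite")
  if (nrow(ccdVec) != nrow(ncdVec))
    stop("ccdVec and ncdVec must have the same number of rows")
  ccd <- sqrt(rowSums(ccdVec^2))
  deg <- ccd <= .tolZero
  ncdPar <- numeric(length(ccd))
  if (any(!deg))
    ncdPar[!deg] <- rowSums(ccdVec[!deg, , drop = FALSE] *
                            ncdVec[!deg, , drop = FALSE]) / ccd[!deg]
  if (any(deg))
    ncdPar[deg] <- sqrt(rowSums(ncdVec[deg, , drop = FALSE]^2))
  list(ccd = ccd, ncdPar = ncdPar, degenerate = deg)
}

#' Polar angle of a CN-correlation point
#'
#' theta = atan2(CCD, NCD//) in degrees, the polar angle of the point in
#' the plane with NCD// as abscissa and CCD as ordinate. Pure protrusion
#' (NCD// = 0) sits at 90 degrees; detachment (NCD// > CCD > 0) below 45.
#' Zero CCD yields NA.
#'
#' @param ccd,ncdPar numeric vectors (um).
#' @return Angle(s) in degrees, in (0, 180] for CCD > 0.
#' @export
cnAngle <- function(ccd, ncdPar) {
  if (!all(is.finite(ccd)) || !all(is.finite(ncdPar)))
    stop("ccd and ncdPar must be finite")
  th <- atan2(ccd, ncdPar) * 180 / pi
  th[ccd <= .tolZero] <- NA_real_
  th
}

#' Classify an interval into an angular region
#'
#' Region I (0 < theta <= 45): detachment mode; Region II (45 < theta <=
#' 75): mixed detachment/protrusion; Region III (75 < theta <= 105):
#' protrusion/retraction; Region IV (105 < theta <= 180): large-angle side
#' protrusion. Boundary angles belong to the lower-numbered region (closed
#' upper bound). CCD = 0 gives UNDEFINED.
#'
#' @param ccd,ncdPar numeric vectors (um).
#' @return Character vector of region labels.
#' @examples
#' classifyRegion(1, 1)    # theta = 45 -> "I"
#' classifyRegion(1, 0)    # theta = 90 -> "III"
#' @export
classifyRegion <- function(ccd, ncdPar) {
  if (any(ccd < 0)) stop("ccd must be non-negative")
  th <- cnAngle(ccd, ncdPar)
  out <- rep("UNDEFINED", length(th))
  ok <- !is.na(th)
  out[ok & th <= 45] <- "I"
  out[ok & th > 45 & th <= 75] <- "II"
  out[ok & th > 75 & th <= 105] <- "III"
  out[ok & th > 105] <- "IV"
  out
}

#' Compute the CN-correlation series of a trajectory pair
#'
#' Composes \code{\link{displacementPairs}}, \code{\link{projectNCD}} and
#' \code{\link{classifyRegion}} in interval order.
#'
#' @param traj a \linkS4class{TrajectoryPair}.
#' @param lagSteps frames per interval (default 1).
#' @return A \linkS4class{CNSeries}.
#' @export
cnSeriesFromTrajectory <- function(traj, lagSteps = 1L) {
  dp <- displacementPairs(traj, lagSteps)
  pr <- projectNCD(dp$cell, dp$nuc)
  newCNSeries(traj@cellId, samplingTau(traj) * as.integer(lagSteps),
              pr$ccd, pr$ncdPar)
}

# Build a CNSeries from raw ccd / ncd_par values (internal constructor).
newCNSeries <- function(cellId, tau, ccd, ncdPar, intervalIndex = NULL) {
  if (is.null(intervalIndex)) intervalIndex <- seq_along(ccd)
  new("CNSeries", cellId = as.character(cellId), tau = tau,
      points = data.frame(
        interval_index = as.integer(intervalIndex),
        ccd = ccd,
        ncd_par = ncdPar,
        theta = cnAngle(ccd, ncdPar),
        region = classifyRegion(ccd, ncdPar),
        stringsAsFactors = FALSE))
}

#' Normalized autocorrelation of a CN observable
#'
#' Sample autocorrelation r(k) = sum_t (x_t - xbar)(x_{t+k} - xbar) /
#' sum_t (x_t - xbar)^2 for lags 0..maxLag, the diagnostic applied to the
#' theta and NCD// sequences of a CN series. NA entries (UNDEFINED
#' intervals) are excluded pairwise. A zero-variance (constant) series
#' returns 1 at every lag by convention.
#'
#' @param values numeric vector (NA allowed).
#' @param maxLag maximum lag; series must have more than maxLag + 2
#'   non-missing values.
#' @return Numeric vector of length maxLag + 1 (lags 0..maxLag).
#' @export
seriesAutocorrelation <- function(values, maxLag) {
  maxLag <- as.integer(maxLag)
  x <- as.numeric(values)
  nOk <- sum(!is.na(x))
  if (nOk <= maxLag + 2L)
    stop("series too short: need more than maxLag + 2 non-missing values")
  xb <- mean(x, na.rm = TRUE)
  d <- x - xb
  denom <- sum(d^2, na.rm = TRUE)
  if (denom <= .tolZero * max(1, xb^2))
    return(rep(1, maxLag + 1L))
  n <- length(d)
  vapply(0:maxLag, function(k) {
    a <- d[seq_len(n - k)]
    b <- d[seq_len(n - k) + k]
    sum(a * b, na.rm = TRUE) / denom
  }, numeric(1))
}
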