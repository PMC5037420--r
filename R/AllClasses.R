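#' @import methods
NULL

#' Region labels used throughout the package
#'
#' Angular regions of the CCD vs. NCD// plane: \code{I} detachment
#' (0 < theta <= 45 deg), \code{II} mixed detachment/protrusion
#' (45 < theta <= 75), \code{III} protrusion/retraction (75 < theta <= 105),
#' \code{IV} large-angle side protrusion (105 < theta <= 180), \code{V}
#' stationary mode (assigned by the Monte-Carlo noise filter only) and
#' \code{UNDEFINED} for intervals whose cell displacement is exactly zero.
#'
#' @return Character vector of the six region labels, in canonical order.
#' @export
regionLevels <- function() c("I", "II", "III", "IV", "V", "UNDEFINED")

#' Barcode colors by region
#'
#' Fixed color convention: Region I red, II yellow, III blue, IV green,
#' V black. UNDEFINED intervals are drawn as gaps.
#'
#' @return Named character vector mapping region to color.
#' @export
regionColors <- function() {
  c(I = "red", II = "yellow", III = "blue", IV = "green", V = "black")
}

.tolZero <- 1e-12   # |CCD| below this is treated as a zero displacement

#' TrajectoryPair: paired cell and nucleus centroid tracks
#'
#' Time-stamped 2-D centroid trajectories of one cell and its nucleus,
#' sampled on a uniform grid. Positions are in micrometres, times in
#' minutes. The time column is authoritative; frame indices are
#' bookkeeping only.
#'
#' @slot cellId character(1), opaque cell identifier.
#' @slot times numeric, strictly increasing, uniformly spaced (minutes).
#' @slot cellXY T x 2 numeric matrix of cell centroid positions (um).
#' @slot nucXY T x 2 numeric matrix of nucleus centroid positions (um).
#'
#' @export
setClass("TrajectoryPair",
  representation(
    cellId = "character",
    times  = "numeric",
    cellXY = "matrix",
    nucXY  = "matrix"
  )
)

setValidity("TrajectoryPair", function(object) {
  msgs <- character()
  tt <- object@times
  if (length(object@cellId) != 1L) msgs <- c(msgs, "cellId must be length 1")
  if (length(tt) < 2L) msgs <- c(msgs, "a trajectory needs at least 2 time points")
  if (length(tt) >= 2L) {
    dt <- diff(tt)
    if (any(dt <= 0)) msgs <- c(msgs, "times must be strictly increasing")
    else {
      rel <- abs(dt - dt[1L]) / dt[1L]
      if (any(rel > 1e-9))
        msgs <- c(msgs, sprintf(
          "non-uniform time spacing at frame index %d",
          which(rel > 1e-9)[1L] + 1L))
    }
  }
  for (nm in c("cellXY", "nucXY")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || ncol(m) != 2L)
      msgs <- c(msgs, sprintf("%s must be a numeric T x 2 matrix", nm))
    else {
      if (nrow(m) != length(tt))
        msgs <- c(msgs, sprintf("%s must have one row per time point", nm))
      if (!all(is.finite(m)))
        msgs <- c(msgs, sprintf("%s contains non-finite values", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CNSeries: per-interval cell-nucleus correlation points
#'
#' One row per fixed-length interval of a trajectory: the magnitude of the
#' cell centroid displacement (CCD, um), the signed projection of the
#' nucleus centroid displacement onto the CCD direction (NCD//, um), the
#' polar angle theta = atan2(CCD, NCD//) in degrees, and the region label.
#' Intervals with CCD = 0 carry region \code{UNDEFINED}, \code{NA} theta,
#' and report |NCD| in the ncd_par column (degenerate projection).
#'
#' @slot cellId character(1).
#' @slot tau sampling interval in minutes.
#' @slot points data.frame with columns \code{interval_index}, \code{ccd},
#'   \code{ncd_par}, \code{theta}, \code{region} and, after the stationary
#'   filter has run, \code{region_original} and \code{noise_p}.
#'
#' @export
setClass("CNSeries",
  representation(
    cellId = "character",
    tau    = "numeric",
    points = "data.frame"
  )
)

setValidity("CNSeries", function(object) {
  msgs <- character()
  p <- object@points
  need <- c("interval_index", "ccd", "ncd_par", "theta", "region")
  miss <- setdiff(need, names(p))
  if (length(miss))
    return(sprintf("points is missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(p) < 1L) msgs <- c(msgs, "points must have at least one row")
  if (any(p$ccd < 0)) msgs <- c(msgs, "ccd must be non-negative")
  if (!all(p$region %in% regionLevels()))
    msgs <- c(msgs, "invalid region label in points")
  def <- p$region != "UNDEFINED"
  if (any(def) && (any(!is.finite(p$theta[def])) ||
                   any(p$theta[def] <= 0) || any(p$theta[def] > 180)))
    msgs <- c(msgs, "theta of defined points must lie in (0, 180] degrees")
  if (length(object@tau) != 1L || object@tau <= 0)
    msgs <- c(msgs, "tau must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Barcode: time-ordered region labels for one cell
#'
#' @slot cellId character(1).
#' @slot tau sampling interval in minutes.
#' @slot labels character vector of region labels, one per interval.
#' @slot scheme \code{"four"} (Regions I-IV) or \code{"five"} (I-V).
#'
#' @export
setClass("Barcode",
  representation(
    cellId = "character",
    tau    = "numeric",
    labels = "character",
    scheme = "character"
  )
)

setValidity("Barcode", function(object) {
  msgs <- character()
  if (!object@scheme %in% c("four", "five"))
    msgs <- c(msgs, "scheme must be 'four' or 'five'")
  if (length(object@labels) < 1L)
    msgs <- c(msgs, "a barcode needs at least one label")
  allowed <- if (identical(object@scheme, "five"))
    regionLevels() else setdiff(regionLevels(), "V")
  bad <- setdiff(unique(object@labels), allowed)
  if (length(bad))
    msgs <- c(msgs, sprintf("label(s) %s not valid for the %s-region scheme",
                            paste(bad, collapse = ", "), object@scheme))
  if (length(msgs)) msgs else TRUE
})

#' CMPIResult: Cell Migration Potential Index for one cell
#'
#' CMPI = sum over Regions I and II of (occurrence fraction x mean NCD//),
#' in micrometres per interval at the stated sampling interval tau.
#' Occurrence fractions are taken over defined (non-UNDEFINED) intervals.
#'
#' @slot cellId character(1).
#' @slot occurrence named numeric, occurrence fraction per region.
#' @slot regionMeanNcdPar named numeric, mean NCD// per region (0 if empty).
#' @slot cmpi numeric(1), um per interval.
#' @slot tau minutes.
#' @slot nIntervals integer, number of defined intervals used.
#'
#' @export
setClass("CMPIResult",
  representation(
    cellId = "character",
    occurrence = "numeric",
    regionMeanNcdPar = "numeric",
    cmpi = "numeric",
    tau = "numeric",
    nIntervals = "integer"
  )
)

setValidity("CMPIResult", function(object) {
  msgs <- character()
  o <- object@occurrence
  m <- object@regionMeanNcdPar
  if (!all(c("I", "II") %in% names(o)) || !all(c("I", "II") %in% names(m)))
    msgs <- c(msgs, "occurrence and regionMeanNcdPar must name Regions I and II")
  else {
    ref <- sum(o[c("I", "II")] * m[c("I", "II")])
    if (!isTRUE(abs(object@cmpi - ref) <= 1e-9 * max(1, abs(ref))))
      msgs <- c(msgs, "cmpi does not equal sum_{i in I,II} o_i * <NCD//>_i")
  }
  if (object@nIntervals < 1L) msgs <- c(msgs, "nIntervals must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' NoiseDensity: empirical positioning-noise distribution
#'
#' A 2-D histogram of fixed-cell (NCD//, CCD) points, normalized so every
#' bin value lies in [0, 1]; queried as a piecewise-constant noise
#' probability p(NCD//, CCD). Out-of-hull queries return 0.
#'
#' @slot edgesNcdPar bin edges along NCD// (um).
#' @slot edgesCcd bin edges along CCD (um).
#' @slot pGrid matrix of noise probabilities, rows index NCD// bins,
#'   columns index CCD bins.
#' @slot nSourcePoints number of fixed-cell points the grid was fit on.
#' @slot normalization \code{"max"} (mode maps to 1) or \code{"frequency"}
#'   (bin relative frequencies).
#'
#' @export
setClass("NoiseDensity",
  representation(
    edgesNcdPar = "numeric",
    edgesCcd = "numeric",
    pGrid = "matrix",
    nSourcePoints = "integer",
    normalization = "character"
  )
)

setValidity("NoiseDensity", function(object) {
  msgs <- character()
  if (nrow(object@pGrid) != length(object@edgesNcdPar) - 1L ||
      ncol(object@pGrid) != length(object@edgesCcd) - 1L)
    msgs <- c(msgs, "pGrid dimensions must match the bin edges")
  if (any(object@pGrid < 0) || any(object@pGrid > 1))
    msgs <- c(msgs, "pGrid values must lie in [0, 1]")
  if (is.unsorted(object@edgesNcdPar, strictly = TRUE) ||
      is.unsorted(object@edgesCcd, strictly = TRUE))
    msgs <- c(msgs, "bin edges must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' MSDCurve: mean-squared displacement by time lag
#'
#' @slot lags time lags in minutes (starting at tau; no zero lag).
#' @slot msd mean-squared displacement per lag (um^2).
#' @slot nPairs number of displacement pairs averaged at each lag.
#' @slot overlapping logical, whether overlapping start points were used.
#'
#' @export
setClass("MSDCurve",
  representation(
    lags = "numeric",
    msd = "numeric",
    nPairs = "integer",
    overlapping = "logical"
  )
)

setValidity("MSDCurve", function(object) {
  msgs <- character()
  if (length(object@lags) != length(object@msd) ||
      length(object@lags) != length(object@nPairs))
    msgs <- c(msgs, "lags, msd and nPairs must have equal length")
  if (any(object@msd < 0)) msgs <- c(msgs, "msd must be non-negative")
  if (is.unsorted(object@lags, strictly = TRUE) || any(object@lags <= 0))
    msgs <- c(msgs, "lags must be positive and strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' PRWFit: persistent-random-walk parameters fitted to an MSD curve
#'
#' Fuerth model msd(t) = 2 S^2 P [t - P (1 - exp(-t/P))] with
#' root-mean-square speed S (um/min) and persistence time P (min); the
#' motility diffusion coefficient is mu = S^2 P / n with n = 2 dimensions.
#'
#' @slot S um/min.
#' @slot P minutes.
#' @slot mu um^2/min, always equal to S^2 * P / 2.
#' @slot nDim integer, spatial dimension (2).
#' @slot residualNorm residual sum of squares of the fit.
#' @slot converged logical.
#' @slot message diagnostic text (convergence status, degenerate regimes).
#'
#' @export
setClass("PRWFit",
  representation(
    S = "numeric",
    P = "numeric",
    mu = "numeric",
    nDim = "integer",
    residualNorm = "numeric",
    converged = "logical",
    message = "character"
  )
)

setValidity("PRWFit", function(object) {
  if (isTRUE(object@converged)) {
    if (!(object@S > 0 && object@P > 0))
      return("S and P must be positive on a converged fit")
    mu <- object@S^2 * object@P / object@nDim
    if (abs(object@mu - mu) > 1e-9 * max(1, mu))
      return("mu must equal S^2 * P / nDim")
  }
  TRUE
})

#' EventScript: scripted per-interval kinematics for the event simulator
#'
#' Each interval carries one event label. Kinematics: \code{protrusion}
#' moves the cell centroid by \code{cellStep} while the nucleus is static;
#' \code{retraction} is the same with the cell step reversed;
#' \code{detachment} moves cell and nucleus together with the nucleus step
#' equal to \code{detachRatio} x cell step (ratio > 1: the nucleus
#' translates further than the whole-cell centroid); \code{mixed} moves
#' both with the nucleus step a fraction \code{mixedFraction} of the cell
#' step; \code{turn} rotates the cell step by \code{turnAngle} (> 90 deg)
#' while the nucleus keeps a small step in the old direction;
#' \code{stationary} moves neither. Isotropic Gaussian jitter of sd
#' \code{jitterSigma} is added to both positions.
#'
#' @slot events character vector of event labels, one per interval.
#' @slot cellStep um, cell centroid step per event interval (recycled).
#' @slot detachRatio nucleus/cell step ratio for detachment events (> 1).
#' @slot mixedFraction nucleus/cell step ratio for mixed events (in (0, 1]).
#' @slot turnAngle degrees in (90, 180], heading change of a turn event.
#' @slot turnNucFraction nucleus step (fraction of cellStep) during a turn,
#'   taken in the pre-turn direction.
#' @slot direction0 initial heading, degrees.
#' @slot jitterSigma um, positional jitter sd per axis per frame.
#' @slot tau minutes per interval.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("EventScript",
  representation(
    events = "character",
    cellStep = "numeric",
    detachRatio = "numeric",
    mixedFraction = "numeric",
    turnAngle = "numeric",
    turnNucFraction = "numeric",
    direction0 = "numeric",
    jitterSigma = "numeric",
    tau = "numeric",
    seed = "integer"
  )
)

.eventNames <- c("protrusion", "retraction", "detachment", "mixed",
                 "turn", "stationary")

setValidity("EventScript", function(object) {
  msgs <- character()
  bad <- setdiff(unique(object@events), .eventNames)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown event name(s): %s",
                            paste(bad, collapse = ", ")))
  if (any(object@cellStep < 0)) msgs <- c(msgs, "cellStep must be >= 0")
  if (object@detachRatio <= 1) msgs <- c(msgs, "detachRatio must exceed 1")
  if (object@turnAngle <= 90 || object@turnAngle > 180)
    msgs <- c(msgs, "turnAngle must lie in (90, 180] degrees")
  if (object@jitterSigma < 0) msgs <- c(msgs, "jitterSigma must be >= 0")
  if (object@tau <= 0) msgs <- c(msgs, "tau must be positive")
  if (length(msgs)) msgs else TRUE
})

#' NoiseSweepResult: noise-implemented CMPI against injected noise sd
#'
#' @slot sigmas injected Gaussian noise standard deviations (um).
#' @slot meanCMPI mean noise-implemented population CMPI per sigma.
#' @slot repeats number of noise realizations averaged per sigma.
#' @slot tau minutes.
#' @slot seed integer seed used.
#'
#' @export
setClass("NoiseSweepResult",
  representation(
    sigmas = "numeric",
    meanCMPI = "numeric",
    repeats = "integer",
    tau = "numeric",
    seed = "integer"
  )
)

setValidity("NoiseSweepResult", function(object) {
  if (length(object@sigmas) != length(object@meanCMPI))
    return("one meanCMPI per sigma required")
  if (object@repeats < 1L) return("repeats must be >= 1")
  TRUE
})
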