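# Generics and accessors. Slot access everywhere else goes through these.

#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("samplingTau", function(x) standardGeneric("samplingTau"))

#' @rdname accessors
#' @export
setGeneric("trackTimes", function(x) standardGeneric("trackTimes"))

#' @rdname accessors
#' @export
setGeneric("cellTrack", function(x) standardGeneric("cellTrack"))

#' @rdname accessors
#' @export
setGeneric("nucTrack", function(x) standardGeneric("nucTrack"))

#' @rdname accessors
#' @export
setGeneric("cnPoints", function(x) standardGeneric("cnPoints"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("barcodeScheme", function(x) standardGeneric("barcodeScheme"))

#' @rdname accessors
#' @export
setGeneric("cmpiValue", function(x) standardGeneric("cmpiValue"))

#' @rdname accessors
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))

#' Region occurrence fractions
#'
#' Fraction of defined (non-UNDEFINED) intervals falling in each region of
#' the object's scheme. Fractions sum to 1 over the scheme's regions.
#'
#' @param x a \linkS4class{Barcode}, \linkS4class{CNSeries}, or character
#'   vector of region labels.
#' @param ... passed to methods; character method accepts
#'   \code{scheme = "four"/"five"}.
#' @return Named numeric vector of occurrence fractions.
#' @export
setGeneric("regionOccurrence", function(x, ...) standardGeneric("regionOccurrence"))

#' Accessors for cnmotility S4 classes
#'
#' \code{cellId}, \code{samplingTau}, \code{trackTimes}, \code{cellTrack},
#' \code{nucTrack} read \linkS4class{TrajectoryPair} slots; \code{cnPoints}
#' returns the per-interval data.frame of a \linkS4class{CNSeries};
#' \code{regionLabels} and \code{barcodeScheme} read a
#' \linkS4class{Barcode}; \code{cmpiValue} and \code{occurrence} read a
#' \linkS4class{CMPIResult}.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("cellId", "TrajectoryPair", function(x) x@cellId)
#' @rdname accessors
setMethod("cellId", "CNSeries", function(x) x@cellId)
#' @rdname accessors
setMethod("cellId", "Barcode", function(x) x@cellId)
#' @rdname accessors
setMethod("cellId", "CMPIResult", function(x) x@cellId)

#' @rdname accessors
setMethod("samplingTau", "TrajectoryPair", function(x) diff(x@times[1:2]))
#' @rdname accessors
setMethod("samplingTau", "CNSeries", function(x) x@tau)
#' @rdname accessors
setMethod("samplingTau", "Barcode", function(x) x@tau)
#' @rdname accessors
setMethod("samplingTau", "CMPIResult", function(x) x@tau)

#' @rdname accessors
setMethod("trackTimes", "TrajectoryPair", function(x) x@times)
#' @rdname accessors
setMethod("cellTrack", "TrajectoryPair", function(x) x@cellXY)
#' @rdname accessors
setMethod("nucTrack", "TrajectoryPair", function(x) x@nucXY)

#' @rdname accessors
setMethod("cnPoints", "CNSeries", function(x) x@points)

#' @rdname accessors
setMethod("regionLabels", "Barcode", function(x) x@labels)
#' @rdname accessors
setMethod("regionLabels", "CNSeries", function(x) x@points$region)
#' @rdname accessors
setMethod("barcodeScheme", "Barcode", function(x) x@scheme)

#' @rdname accessors
setMethod("cmpiValue", "CMPIResult", function(x) x@cmpi)
#' @rdname accessors
setMethod("occurrence", "CMPIResult", function(x) x@occurrence)

setMethod("show", "TrajectoryPair", function(object) {
  tt <- object@times
  cat(sprintf(
    "TrajectoryPair '%s': %d frames, tau = %g min, %.1f min total\n",
    object@cellId, length(tt), diff(tt[1:2]), tt[length(tt)] - tt[1]))
})

setMethod("show", "CNSeries", function(object) {
  p <- object@points
  def <- sum(p$region != "UNDEFINED")
  cat(sprintf("CNSeries '%s': %d intervals (%d defined), tau = %g min\n",
              object@cellId, nrow(p), def, object@tau))
  tab <- table(factor(p$region, levels = regionLevels()))
  print(tab[tab > 0])
})

setMethod("show", "Barcode", function(object) {
  cat(sprintf("Barcode '%s': %d bars, %s-region scheme, tau = %g min\n",
              object@cellId, length(object@labels), object@scheme,
              object@tau))
})

setMethod("show", "CMPIResult", function(object) {
  cat(sprintf("CMPIResult '%s': CMPI = %.4g um/interval (tau = %g min, %d intervals)\n",
              object@cellId, object@cmpi, object@tau, object@nIntervals))
  cat("  occurrence:",
      paste(sprintf("%s=%.3f", names(object@occurrence), object@occurrence),
            collapse = " "), "\n")
})

setMethod("show", "NoiseDensity", function(object) {
  cat(sprintf(
    "NoiseDensity: %d x %d bins (%s-normalized) from %d fixed-cell points\n",
    nrow(object@pGrid), ncol(object@pGrid), object@normalization,
    object@nSourcePoints))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lags in [%g, %g] min, %s start points\n",
              length(object@lags), object@lags[1],
              object@lags[length(object@lags)],
              if (object@overlapping) "overlapping" else "non-overlapping"))
})

setMethod("show", "PRWFit", function(object) {
  if (isTRUE(object@converged))
    cat(sprintf(
      "PRWFit: S = %.4g um/min, P = %.4g min, mu = %.4g um^2/min (%s)\n",
      object@S, object@P, object@mu, object@message))
  else
    cat(sprintf("PRWFit: NOT converged (%s)\n", object@message))
})

setMethod("show", "NoiseSweepResult", function(object) {
  cat(sprintf(
    "NoiseSweepResult: %d sigma values in [%g, %g] um, %d repeats, tau = %g min\n",
    length(object@sigmas), min(object@sigmas), max(object@sigmas),
    object@repeats, object@tau))
})
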