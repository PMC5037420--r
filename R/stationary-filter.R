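# Monte-Carlo stationary-mode filter: empirical fixed-cell noise density,
# per-point noise probability, region-V reassignment, prolonged runs.

#' Fit the empirical positioning-noise density from fixed-cell CN data
#'
#' Bins the (NCD//, CCD) points of a fixed (immobile) cell into a 2-D
#' histogram over their data hull. With the default \code{"max"}
#' normalization the histogram is divided by its largest count, so the
#' modal bin maps to noise probability 1: a live-cell displacement
#' indistinguishable from the most probable pure-noise outcome is treated
#' as almost surely noise. The \code{"frequency"} alternative uses bin
#' relative frequencies (counts / total).
#'
#' @param fixedPoints a \linkS4class{CNSeries} from fixed-cell data, or a
#'   data.frame with columns \code{ncd_par} and \code{ccd}.
#' @param bins bins per axis (default 32, minimum 4).
#' @param normalization \code{"max"} (default) or \code{"frequency"}.
#' @return A \linkS4class{NoiseDensity}.
#' @export
fitNoiseDensity <- function(fixedPoints, bins = 32L,
                            normalization = c("max", "frequency")) {
  normalization <- match.arg(normalization)
  bins <- as.integer(bins)
  if (bins < 4L) stop("need at least 4 bins per axis")
  p <- if (is(fixedPoints, "CNSeries")) fixedPoints@points else fixedPoints
  keep <- p$region != "UNDEFINED" & is.finite(p$ncd_par) & is.finite(p$ccd)
  x <- p$ncd_par[keep]
  y <- p$ccd[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 defined fixed-cell points")
  if (n < 100L)
    warning("only ", n, " fixed-cell points; the noise density will be coarse")
  ex <- seq(min(x), max(x), length.out = bins + 1L)
  ey <- seq(min(y), max(y), length.out = bins + 1L)
  # guard degenerate (all-equal) axes
  if (ex[1] == ex[bins + 1L]) ex <- ex[1] + seq(-1, 1, length.out = bins + 1L) * 1e-6
  if (ey[1] == ey[bins + 1L]) ey <- ey[1] + seq(-1, 1, length.out = bins + 1L) * 1e-6
  ix <- .binIndex(x, ex)
  iy <- .binIndex(y, ey)
  counts <- matrix(0, bins, bins)
  for (k in seq_len(n)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  pGrid <- switch(normalization,
                  max = counts / max(counts),
                  frequency = counts / sum(counts))
  new("NoiseDensity", edgesNcdPar = ex, edgesCcd = ey, pGrid = pGrid,
      nSourcePoints = as.integer(n), normalization = normalization)
}

# Bin lookup with the documented tie-break: a value on an interior edge
# belongs to the lower-index bin; the minimum edge belongs to bin 1.
# Returns 0 for out-of-range values.
.binIndex <- function(v, edges) {
  i <- findInterval(v, edges, left.open = TRUE)
  i[v == edges[1L]] <- 1L
  i[i >= length(edges)] <- 0L          # beyond the last edge
  i[v > edges[length(edges)]] <- 0L
  i
}

#' Noise probability of a CN point
#'
#' Piecewise-constant lookup of p(NCD//, CCD) in the fitted noise density.
#' Points outside the fixed-cell data hull have probability 0; a point on a
#' bin edge is assigned to the lower-index bin.
#'
#' @param density a \linkS4class{NoiseDensity}.
#' @param ncdPar,ccd numeric vectors (um), or a \linkS4class{CNSeries} as
#'   \code{ncdPar} with \code{ccd} missing.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
noiseProbability <- function(density, ncdPar, ccd) {
  stopifnot(is(density, "NoiseDensity"))
  if (missing(ccd) && is(ncdPar, "CNSeries")) {
    pts <- ncdPar@points
    ncdPar <- pts$ncd_par
    ccd <- pts$ccd
  }
  ix <- .binIndex(ncdPar, density@edgesNcdPar)
  iy <- .binIndex(ccd, density@edgesCcd)
  out <- numeric(length(ncdPar))
  ok <- ix > 0L & iy > 0L
  out[ok] <- density@pGrid[cbind(ix[ok], iy[ok])]
  out
}

#' Monte-Carlo reassignment of likely-noise intervals to Region V
#'
#' For every interval, one uniform [0, 1] deviate u is drawn (in interval
#' order, from a single seeded stream). If u exceeds the interval's noise
#' probability p(NCD//, CCD) the original region is kept (effective motion);
#' otherwise the interval is reassigned to Region V (stationary mode).
#' Reassignment only ever maps Regions I-IV to V; UNDEFINED intervals are
#' untouched (their draw is still consumed, keeping the stream aligned).
#'
#' @param x a \linkS4class{CNSeries}.
#' @param density a \linkS4class{NoiseDensity} from fixed-cell data.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A \linkS4class{CNSeries} whose points carry the new
#'   \code{region}, the original labels in \code{region_original} and the
#'   per-point noise probability in \code{noise_p}.
#' @export
monteCarloFilter <- function(x, density, seed) {
  stopifnot(is(x, "CNSeries"), is(density, "NoiseDensity"))
  p <- x@points
  np <- noiseProbability(density, p$ncd_par, p$ccd)
  u <- withSeed(seed, stats::runif(nrow(p)))
  reassign <- u <= np & p$region %in% c("I", "II", "III", "IV")
  out <- x
  out@points$region_original <- p$region
  out@points$noise_p <- np
  out@points$region[reassign] <- "V"
  out
}

#' Prolonged stationary segments
#'
#' Maximal runs of Region V strictly longer than \code{minRun} intervals.
#' Short stationary stretches (a few intervals) are part of normal
#' locomotion; only prolonged ones mark a genuinely stationary cell.
#'
#' @param labels character vector of region labels, or a
#'   \linkS4class{Barcode} / \linkS4class{CNSeries}.
#' @param minRun runs must exceed this length (default 5 intervals).
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   interval indices, inclusive) and \code{length}; zero rows if none.
#' @export
prolongedStationarySegments <- function(labels, minRun = 5L) {
  if (is(labels, "Barcode")) labels <- labels@labels
  if (is(labels, "CNSeries")) labels <- labels@points$region
  r <- rle(labels == "V")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > as.integer(minRun)
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}
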