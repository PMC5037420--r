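# Internal helpers.

# Run code with a temporary RNG state; restores the caller's .Random.seed.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}

#' Construct a TrajectoryPair
#'
#' @param cellId cell identifier (coerced to character).
#' @param times time stamps in minutes, strictly increasing and uniformly
#'   spaced.
#' @param cellXY,nucXY T x 2 matrices (or 2-column data.frames) of cell and
#'   nucleus centroid positions in micrometres.
#' @return A \linkS4class{TrajectoryPair}.
#' @examples
#' tp <- trajectoryPair("c1", 0:3, cbind(0:3, 0), cbind(0:3 / 2, 0))
#' samplingTau(tp)
#' @export
trajectoryPair <- function(cellId, times, cellXY, nucXY) {
  toMat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
  new("TrajectoryPair", cellId = as.character(cellId),
      times = as.numeric(times), cellXY = toMat(cellXY), nucXY = toMat(nucXY))
}

# Subsample a trajectory to every `factor`-th frame (emulates coarser tau).
#' Subsample a trajectory to a coarser sampling interval
#'
#' Keeps every \code{factor}-th frame, exactly equivalent to having
#' acquired the movie at \code{factor * tau} minutes.
#'
#' @param traj a \linkS4class{TrajectoryPair}.
#' @param factor positive integer subsampling factor.
#' @return A \linkS4class{TrajectoryPair} at the coarser spacing.
#' @export
subsampleTrajectory <- function(traj, factor) {
  stopifnot(is(traj, "TrajectoryPair"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("subsampling factor must be a positive integer")
  idx <- seq(1L, length(traj@times), by = factor)
  if (length(idx) < 2L)
    stop("trajectory too short for subsampling factor ", factor)
  trajectoryPair(traj@cellId, traj@times[idx],
                 traj@cellXY[idx, , drop = FALSE],
                 traj@nucXY[idx, , drop = FALSE])
}

# Degrees-based trig used by the simulators.
unitVec <- function(deg) {
  r <- deg * pi / 180
  c(cos(r), sin(r))
}
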