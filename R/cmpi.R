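# Cell Migration Potential Index: per-cell value, population summary,
# running window and sample-size convergence.

#' Cell Migration Potential Index of one cell
#'
#' CMPI = sum over Regions I and II of o_i * <NCD//>_i, where o_i is the
#' occurrence fraction of region i over defined intervals and <NCD//>_i the
#' mean NCD// within the region (taken as 0 when the region is empty).
#' Equivalently, CMPI is the sum of NCD// over intervals with
#' 0 < theta <= 75 degrees, divided by the number of defined intervals —
#' the effective nuclear translocation per interval. Regions III-V do not
#' contribute.
#'
#' @param x a \linkS4class{CNSeries}.
#' @param scheme \code{"four"} (default) or \code{"five"}; with
#'   \code{"five"}, intervals filtered to Region V count in the denominator
#'   but contribute no NCD//.
#' @return A \linkS4class{CMPIResult} (um per interval at the series' tau).
#' @export
cellCMPI <- function(x, scheme = c("four", "five")) {
  stopifnot(is(x, "CNSeries"))
  scheme <- match.arg(scheme)
  p <- x@points
  if (scheme == "four" && any(p$region == "V"))
    stop("series contains Region V labels; use scheme = \"five\"")
  regions <- if (scheme == "five") c("I", "II", "III", "IV", "V")
             else c("I", "II", "III", "IV")
  def <- p$region != "UNDEFINED"
  if (!any(def)) stop("no defined intervals in the series")
  nDef <- sum(def)
  occ <- vapply(regions, function(r) sum(p$region == r) / nDef, numeric(1))
  mns <- vapply(regions, function(r) {
    v <- p$ncd_par[p$region == r]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  new("CMPIResult", cellId = x@cellId, occurrence = occ,
      regionMeanNcdPar = mns,
      cmpi = sum(occ[c("I", "II")] * mns[c("I", "II")]),
      tau = x@tau, nIntervals = as.integer(nDef))
}

#' Population CMPI: mean and standard error over cells
#'
#' @param results list of \linkS4class{CMPIResult} objects (n >= 2), or a
#'   numeric vector of per-cell CMPI values.
#' @return Named numeric vector \code{c(mean, sem, n)}; SEM = sd/sqrt(n).
#' @export
populationCMPI <- function(results) {
  v <- if (is.numeric(results)) results
       else vapply(results, cmpiValue, numeric(1))
  n <- length(v)
  if (n < 2L) stop("population CMPI needs at least 2 cells (SEM undefined)")
  c(mean = mean(v), sem = stats::sd(v) / sqrt(n), n = n)
}

#' Running-window CMPI
#'
#' CMPI over consecutive windows of \code{windowIntervals} intervals
#' (stride 1). A short window (e.g. 10 intervals) reveals migration
#' details; the full-length window equals the whole-track CMPI. Windows
#' with no defined interval yield NA.
#'
#' @param x a \linkS4class{CNSeries}.
#' @param windowIntervals window length in intervals (<= series length).
#' @return data.frame with columns \code{window_start} (interval index of
#'   the first interval in the window) and \code{cmpi}.
#' @export
runningCMPI <- function(x, windowIntervals) {
  stopifnot(is(x, "CNSeries"))
  p <- x@points
  w <- as.integer(windowIntervals)
  n <- nrow(p)
  if (w < 1L || w > n)
    stop("window (", w, ") must lie between 1 and the series length (", n, ")")
  active <- p$region %in% c("I", "II")
  contrib <- ifelse(active, p$ncd_par, 0)
  def <- as.numeric(p$region != "UNDEFINED")
  # rolling sums via cumulative sums
  cs <- cumsum(c(0, contrib))
  cd <- cumsum(c(0, def))
  starts <- seq_len(n - w + 1L)
  sums <- cs[starts + w] - cs[starts]
  defs <- cd[starts + w] - cd[starts]
  data.frame(window_start = p$interval_index[starts],
             cmpi = ifelse(defs > 0, sums / defs, NA_real_))
}

#' Sample-size convergence of the population CMPI
#'
#' For sample sizes s = step, 2*step, ... up to the pool size, draws s
#' cells without replacement \code{nIterations} times and reports the mean
#' of sample means and the mean sample SEM. The convergence flag marks
#' sample sizes whose mean SEM has fallen below 10\% of the mean — the
#' steady-state criterion for a stable population CMPI.
#'
#' @param pool list of \linkS4class{CMPIResult} objects or numeric vector
#'   of per-cell CMPI values.
#' @param step sample-size increment (default 5).
#' @param nIterations independent random draws per sample size.
#' @param seed integer RNG seed.
#' @param semFraction convergence threshold as a fraction of the mean
#'   (default 0.10).
#' @return data.frame with columns \code{sample_size}, \code{mean},
#'   \code{sem}, \code{converged}; attribute \code{converged_at} holds the
#'   smallest converged sample size (NA if none).
#' @export
convergenceCurve <- function(pool, step = 5L, nIterations = 200L, seed = 1L,
                             semFraction = 0.10) {
  v <- if (is.numeric(pool)) pool else vapply(pool, cmpiValue, numeric(1))
  step <- as.integer(step)
  if (length(v) < step)
    stop("pool (", length(v), " cells) is smaller than the step (", step, ")")
  sizes <- seq(step, length(v), by = step)
  res <- withSeed(seed, {
    t(vapply(sizes, function(s) {
      draws <- vapply(seq_len(nIterations), function(i) {
        smp <- sample(v, s, replace = FALSE)
        c(mean(smp), stats::sd(smp) / sqrt(s))
      }, numeric(2))
      c(mean = mean(draws[1, ]), sem = mean(draws[2, ]))
    }, numeric(2)))
  })
  out <- data.frame(sample_size = sizes, mean = res[, "mean"],
                    sem = res[, "sem"])
  out$converged <- out$sem < semFraction * abs(out$mean)
  attr(out, "converged_at") <-
    if (any(out$converged)) min(out$sample_size[out$converged]) else NA_integer_
  out
}
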