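# On-disk formats. One CSV dialect throughout: UTF-8, header row, "."
# decimal separator, "#"-prefixed comment lines for metadata. Coordinates
# in um, times in minutes.

.trajCols <- c("frame", "time_min", "cell_x_um", "cell_y_um",
               "nuc_x_um", "nuc_y_um", "cell_id")

#' Read paired cell/nucleus trajectories from CSV
#'
#' Expects columns \code{frame, time_min, cell_x_um, cell_y_um, nuc_x_um,
#' nuc_y_um, cell_id} (an optional \code{label} column of ground-truth
#' event names is carried through as an attribute). Rows are sorted by
#' time within each cell; uniform time spacing is enforced. Lines starting
#' with \code{#} are metadata comments.
#'
#' @param path CSV file path.
#' @param tauExpected optional sampling interval (minutes); an error is
#'   raised if the file's spacing disagrees beyond 1e-9 relative.
#' @return Named list of \linkS4class{TrajectoryPair} objects, one per
#'   cell_id.
#' @export
readTrajectories <- function(path, tauExpected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.trajCols, names(df))
  if (length(miss))
    stop("trajectory file is missing required column(s): ",
         paste(miss, collapse = ", "))
  out <- lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
                function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    if (nrow(d) < 2L)
      stop("cell '", d$cell_id[1L], "' has fewer than 2 rows")
    dt <- diff(d$time_min)
    if (any(dt <= 0))
      stop("cell '", d$cell_id[1L], "': duplicated or non-increasing times")
    rel <- abs(dt - dt[1L]) / dt[1L]
    if (any(rel > 1e-9))
      stop("cell '", d$cell_id[1L], "': non-uniform time spacing at frame index ",
           d$frame[which(rel > 1e-9)[1L] + 1L])
    if (!is.null(tauExpected) &&
        abs(dt[1L] - tauExpected) > 1e-9 * tauExpected)
      stop("cell '", d$cell_id[1L], "': spacing ", dt[1L],
           " min does not match the expected tau of ", tauExpected, " min")
    tp <- trajectoryPair(d$cell_id[1L], d$time_min,
                         cbind(d$cell_x_um, d$cell_y_um),
                         cbind(d$nuc_x_um, d$nuc_y_um))
    if ("label" %in% names(df)) attr(tp, "labels") <- d$label[-1L]
    tp
  })
  out
}

#' Write trajectories to CSV
#'
#' Inverse of \code{\link{readTrajectories}}. Simulation parameters (or
#' any metadata) can be emitted as \code{# key: value} comment lines in
#' the header.
#'
#' @param trajs a \linkS4class{TrajectoryPair} or list of them.
#' @param path output CSV path.
#' @param metadata optional named list written as comment lines.
#' @param labels optional per-trajectory character vectors of ground-truth
#'   interval labels (list parallel to \code{trajs}); written as a
#'   \code{label} column (first frame gets NA).
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(trajs, path, metadata = NULL, labels = NULL) {
  if (is(trajs, "TrajectoryPair")) trajs <- list(trajs)
  rows <- lapply(seq_along(trajs), function(i) {
    tp <- trajs[[i]]
    d <- data.frame(frame = seq_along(tp@times),
                    time_min = tp@times,
                    cell_x_um = tp@cellXY[, 1L], cell_y_um = tp@cellXY[, 2L],
                    nuc_x_um = tp@nucXY[, 1L], nuc_y_um = tp@nucXY[, 2L],
                    cell_id = tp@cellId, stringsAsFactors = FALSE)
    if (!is.null(labels)) d$label <- c(NA, labels[[i]])
    d
  })
  df <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, format, character(1))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a CN-correlation table to CSV
#'
#' Columns \code{cell_id, interval_index, ccd_um, ncd_par_um, theta_deg,
#' region}, numeric values printed with 6 decimals; a \code{# tau_min}
#' comment records the sampling interval so the table can be read back.
#'
#' @param x a \linkS4class{CNSeries} or non-empty list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCNTable <- function(x, path) {
  if (is(x, "CNSeries")) x <- list(x)
  if (!length(x)) stop("cannot write an empty CN table")
  stopifnot(all(vapply(x, is, TRUE, "CNSeries")))
  rows <- lapply(x, function(s) {
    p <- s@points
    data.frame(cell_id = s@cellId,
               interval_index = p$interval_index,
               ccd_um = sprintf("%.6f", p$ccd),
               ncd_par_um = sprintf("%.6f", p$ncd_par),
               theta_deg = ifelse(is.na(p$theta), "NA",
                                  sprintf("%.6f", p$theta)),
               region = p$region, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tau_min: %.9g", x[[1L]]@tau), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CN-correlation table from CSV
#'
#' @param path CSV written by \code{\link{writeCNTable}}.
#' @param tau sampling interval in minutes; when missing it is recovered
#'   from the file's \code{# tau_min} comment (default 1 if absent).
#' @return Named list of \linkS4class{CNSeries} objects, one per cell_id.
#' @export
readCNTable <- function(path, tau = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(tau)) {
    head1 <- readLines(path, n = 5L)
    m <- grep("^# tau_min:", head1, value = TRUE)
    tau <- if (length(m)) as.numeric(sub("^# tau_min:", "", m[1L])) else 1
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "interval_index", "ccd_um", "ncd_par_um",
            "theta_deg", "region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CN table is missing required column(s): ",
         paste(miss, collapse = ", "))
  lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
         function(d) {
    d <- d[order(d$interval_index), , drop = FALSE]
    new("CNSeries", cellId = as.character(d$cell_id[1L]), tau = tau,
        points = data.frame(interval_index = as.integer(d$interval_index),
                            ccd = as.numeric(d$ccd_um),
                            ncd_par = as.numeric(d$ncd_par_um),
                            theta = suppressWarnings(as.numeric(d$theta_deg)),
                            region = as.character(d$region),
                            stringsAsFactors = FALSE))
  })
}

#' Run configuration
#'
#' Validated analysis settings, serialized to YAML by
#' \code{\link{writeRunConfig}}.
#'
#' @param tau_min sampling interval, minutes (> 0).
#' @param region_scheme \code{"four"} or \code{"five"}.
#' @param rng_seed integer seed.
#' @param msd_fit_fraction fraction of the maximum lag used in the PRW fit
#'   (in (0, 1]).
#' @param noise_bins histogram bins per axis for the noise density (>= 4).
#' @return A validated named list with class \code{"cn_run_config"}.
#' @export
runConfig <- function(tau_min = 1, region_scheme = "four", rng_seed = 1L,
                      msd_fit_fraction = 0.25, noise_bins = 32L) {
  if (tau_min <= 0) stop("tau_min must be positive")
  if (!region_scheme %in% c("four", "five"))
    stop("region_scheme must be 'four' or 'five'")
  if (msd_fit_fraction <= 0 || msd_fit_fraction > 1)
    stop("msd_fit_fraction must lie in (0, 1]")
  if (noise_bins < 4L) stop("noise_bins must be at least 4 per axis")
  structure(list(tau_min = tau_min, region_scheme = region_scheme,
                 rng_seed = as.integer(rng_seed),
                 msd_fit_fraction = msd_fit_fraction,
                 noise_bins = as.integer(noise_bins),
                 units = list(length = "um", time = "minutes")),
            class = "cn_run_config")
}

#' @rdname runConfig
#' @param config a \code{cn_run_config} object.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "cn_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  runConfig(tau_min = cfg$tau_min, region_scheme = cfg$region_scheme,
            rng_seed = cfg$rng_seed,
            msd_fit_fraction = cfg$msd_fit_fraction,
            noise_bins = cfg$noise_bins)
}
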