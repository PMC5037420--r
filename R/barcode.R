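# Barcode encoding of CN series, occurrence statistics and rendering.

#' Build a barcode from a CN series
#'
#' One bar per interval, in time order, labeled with the interval's region.
#' The four-region scheme covers Regions I-IV; the five-region scheme adds
#' Region V (stationary mode) produced by \code{\link{monteCarloFilter}}.
#'
#' @param x a \linkS4class{CNSeries}.
#' @param scheme \code{"four"} (default) or \code{"five"}.
#' @return A \linkS4class{Barcode}.
#' @export
buildBarcode <- function(x, scheme = c("four", "five")) {
  stopifnot(is(x, "CNSeries"))
  scheme <- match.arg(scheme)
  labels <- x@points$region
  if (scheme == "four" && any(labels == "V"))
    stop("series contains Region V labels; use scheme = \"five\"")
  new("Barcode", cellId = x@cellId, tau = x@tau,
      labels = labels, scheme = scheme)
}

.occurrence <- function(labels, scheme) {
  regions <- if (identical(scheme, "five")) c("I", "II", "III", "IV", "V")
             else c("I", "II", "III", "IV")
  def <- labels[labels != "UNDEFINED"]
  if (!length(def))
    stop("no defined intervals: every label is UNDEFINED")
  counts <- table(factor(def, levels = regions))
  fr <- as.numeric(counts) / length(def)
  names(fr) <- regions
  fr
}

#' @rdname regionOccurrence
setMethod("regionOccurrence", "Barcode", function(x, ...) {
  .occurrence(x@labels, x@scheme)
})

#' @rdname regionOccurrence
setMethod("regionOccurrence", "CNSeries", function(x, ...) {
  labels <- x@points$region
  scheme <- if (any(labels == "V")) "five" else "four"
  .occurrence(labels, scheme)
})

#' @rdname regionOccurrence
#' @param scheme for the character method, \code{"four"} or \code{"five"}.
setMethod("regionOccurrence", "character", function(x, scheme = "four", ...) {
  .occurrence(x, scheme)
})

#' Pooled or per-cell-mean region occurrence over many barcodes
#'
#' Printed population occurrence rates can pool intervals across cells or
#' average per-cell fractions; both are exposed.
#'
#' @param barcodes list of \linkS4class{Barcode} (or
#'   \linkS4class{CNSeries}) objects.
#' @param method \code{"pooled"} (fractions over all intervals of all
#'   cells) or \code{"per_cell_mean"} (mean of per-cell fractions).
#' @param scheme \code{"four"} or \code{"five"}.
#' @return Named numeric vector of occurrence fractions.
#' @export
poolRegionOccurrence <- function(barcodes, method = c("pooled", "per_cell_mean"),
                                 scheme = c("four", "five")) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  labs <- lapply(barcodes, function(b) {
    if (is(b, "Barcode")) b@labels else regionLabels(b)
  })
  if (method == "pooled") {
    .occurrence(unlist(labs), scheme)
  } else {
    fr <- vapply(labs, .occurrence, numeric(if (scheme == "five") 5 else 4),
                 scheme = scheme)
    rowMeans(fr)
  }
}

#' Render a barcode to an image file
#'
#' Horizontal time axis, one row per region of the scheme, bars in the
#' fixed color convention (I red, II yellow, III blue, IV green, V black);
#' UNDEFINED intervals are left as gaps. The format follows the file
#' extension: \code{.png} or \code{.svg}.
#'
#' @param barcode a \linkS4class{Barcode}.
#' @param path output file path ending in .png or .svg.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return \code{path}, invisibly.
#' @export
renderBarcode <- function(barcode, path, width = NULL, height = NULL) {
  stopifnot(is(barcode, "Barcode"))
  ext <- tolower(tools::file_ext(path))
  regions <- if (barcode@scheme == "five") c("I", "II", "III", "IV", "V")
             else c("I", "II", "III", "IV")
  if (ext == "png") {
    if (is.null(width)) width <- 800
    if (is.null(height)) height <- 60 * length(regions) + 60
    grDevices::png(path, width = width, height = height)
  } else if (ext == "svg") {
    if (is.null(width)) width <- 8
    if (is.null(height)) height <- 0.6 * length(regions) + 0.8
    grDevices::svg(path, width = width, height = height)
  } else {
    stop("unsupported image format: .", ext)
  }
  on.exit(grDevices::dev.off())
  cols <- regionColors()
  n <- length(barcode@labels)
  nr <- length(regions)
  graphics::par(mar = c(3.5, 4, 1.5, 1))
  graphics::plot(NA, xlim = c(0, n), ylim = c(0, nr), xaxs = "i", yaxs = "i",
                 axes = FALSE, xlab = "", ylab = "")
  for (k in seq_len(n)) {
    lab <- barcode@labels[k]
    if (lab == "UNDEFINED") next
    row <- nr - match(lab, regions)  # Region I on top
    graphics::rect(k - 1, row + 0.08, k, row + 0.92,
                   col = cols[[lab]], border = NA)
  }
  graphics::axis(1, at = pretty(c(0, n)) * 1,
                 labels = pretty(c(0, n)) * barcode@tau)
  graphics::mtext("time (min)", side = 1, line = 2.2)
  graphics::axis(2, at = rev(seq_len(nr)) - 0.5, labels = regions,
                 las = 1, tick = FALSE)
  graphics::title(main = sprintf("cell %s", barcode@cellId), cex.main = 0.9)
  invisible(path)
}
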