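#' Select the optical plane with peak synaptic colocalization
#'
#' The plasma-membrane analysis is performed on the single plane of the
#' z-series carrying the highest amount of presynaptic/AMPAR colocalization.
#' Ties are broken toward the lowest plane index.
#'
#' @param stack A [confocal_stack()].
#' @param thresholds A [channel_thresholds()].
#' @param exclude Optional integer vector of plane indices to skip (e.g.
#'   planes flagged for staining artifacts).
#' @return 1-based plane index.
#' @export
select_peak_plane <- function(stack, thresholds, exclude = integer()) {
  counts <- stack_counts(stack, thresholds)$per_plane
  ok <- !(counts$plane %in% exclude)
  if (!any(ok)) stop("all planes excluded")
  counts <- counts[ok, ]
  counts$plane[which.max(counts$colocalized)]
}

#' Membrane trace polyline
#'
#' @param vertices Numeric n x 2 matrix of (col, row) pixel coordinates with
#'   at least 3 vertices; closed implicitly (last vertex joins the first).
#' @param source `"auto"` for traces produced by [trace_membrane()],
#'   `"manual"` for researcher-supplied polylines.
#' @return An object of class `membrane_trace`.
#' @export
membrane_trace <- function(vertices, source = c("auto", "manual")) {
  source <- match.arg(source)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a membrane trace needs at least 3 (x, y) vertices")
  structure(list(vertices = vertices, source = source),
            class = "membrane_trace")
}

#' Read a manual membrane trace from CSV
#' @param path CSV with columns `x`, `y` (pixel coordinates, one vertex per
#'   row), as produced by a blinded researcher tracing the membrane.
#' @return A [membrane_trace()] with `source = "manual"`.
#' @export
read_trace <- function(path) {
  tab <- utils::read.csv(path)
  membrane_trace(cbind(tab$x, tab$y), source = "manual")
}

#' Trace the presynaptic-labelled plasma membrane on one plane
#'
#' Automated stand-in for manual membrane tracing: thresholds the
#' presynaptic channel, closes and fills the mask, and returns the contour of
#' the connected region containing the soma centroid. When a manual trace is
#' supplied it is returned unchanged.
#'
#' @param plane Presynaptic-channel matrix of the selected optical plane.
#' @param threshold Presynaptic intensity threshold.
#' @param centroid Soma centroid as (row, col) pixels; the traced contour
#'   must enclose it.
#' @param pixel_size um per pixel (sets the closing radius).
#' @param close_radius Morphological closing radius, um.
#' @param manual Optional [membrane_trace()]; returned as-is when given.
#' @return A [membrane_trace()] in (col, row) pixel coordinates.
#' @export
trace_membrane <- function(plane, threshold, centroid, pixel_size = 0.1,
                           close_radius = 0.5, manual = NULL) {
  if (!is.null(manual)) {
    stopifnot(inherits(manual, "membrane_trace"))
    return(manual)
  }
  stopifnot(is.matrix(plane), length(centroid) == 2L)
  mask <- plane > threshold
  if (!any(mask)) stop("no suprathreshold membrane signal to trace")
  brush_px <- max(3L, 2L * as.integer(round(close_radius / pixel_size)) + 1L)
  m <- EBImage::Image(mask * 1)
  m <- EBImage::closing(m, EBImage::makeBrush(brush_px, shape = "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  labmat <- EBImage::imageData(lab)
  l <- labmat[round(centroid[1L]), round(centroid[2L])]
  if (l == 0) stop("no suprathreshold contour encloses the centroid")
  contours <- EBImage::ocontour(EBImage::Image((labmat == l) * 1))
  verts <- contours[[which.max(vapply(contours, nrow, 1L))]]
  # ocontour returns (row, col) 0-based; convert to (col, row) 1-based
  membrane_trace(cbind(verts[, 2L] + 1L, verts[, 1L] + 1L), source = "auto")
}

#' Membrane band ("optical fraction") mask around a trace
#'
#' Marks every pixel whose Euclidean distance to the membrane polyline is at
#' most `half_width` micrometres, yielding the 2-um-thick plasma-membrane
#' cutout at the default half-width of 1 um.
#'
#' @param trace A [membrane_trace()] in (col, row) pixel coordinates.
#' @param shape Image dimensions `c(rows, cols)`.
#' @param pixel_size um per pixel.
#' @param half_width Band half-width, um (default 1; total thickness 2 um).
#' @param closed Treat the polyline as closed (default TRUE).
#' @return Logical matrix of `shape`; TRUE inside the band.
#' @export
band_cutout <- function(trace, shape, pixel_size = 0.1, half_width = 1,
                        closed = TRUE) {
  stopifnot(inherits(trace, "membrane_trace"), half_width > 0,
            length(shape) == 2L)
  v <- trace$vertices
  if (closed &&
      !isTRUE(all.equal(v[1L, ], v[nrow(v), ], check.attributes = FALSE)))
    v <- rbind(v, v[1L, ])
  if (any(v[, 1L] < 1 | v[, 1L] > shape[2L] | v[, 2L] < 1 | v[, 2L] > shape[1L]))
    warning("membrane trace extends outside the image; band clipped")
  hw_px <- half_width / pixel_size
  d2min <- matrix(Inf, shape[1L], shape[2L])
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    # only pixels inside the segment's padded bounding box can join the band
    cols <- max(1L, floor(min(a[1L], b[1L]) - hw_px)):
      min(shape[2L], ceiling(max(a[1L], b[1L]) + hw_px))
    rows <- max(1L, floor(min(a[2L], b[2L]) - hw_px)):
      min(shape[1L], ceiling(max(a[2L], b[2L]) + hw_px))
    if (!length(cols) || !length(rows)) next
    px <- matrix(rep(cols, each = length(rows)), length(rows))
    py <- matrix(rep(rows, length(cols)), length(rows))
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (px - a[1L])^2 + (py - a[2L])^2
    } else {
      t <- pmin(pmax(((px - a[1L]) * ab[1L] + (py - a[2L]) * ab[2L]) / len2,
                     0), 1)
      d2 <- (px - (a[1L] + t * ab[1L]))^2 + (py - (a[2L] + t * ab[2L]))^2
    }
    d2min[rows, cols] <- pmin(d2min[rows, cols], d2)
  }
  sqrt(d2min) * pixel_size <= half_width
}

#' Classify band pixels as synaptic vs extrasynaptic AMPAR signal
#'
#' Within the plasma-membrane band on the selected plane, total AMPAR pixels
#' are split into synaptic (colocalized with the presynaptic marker) and
#' extrasynaptic (the remainder).
#'
#' @param presynaptic,ampar Matrices of the selected optical plane.
#' @param band Logical band mask from [band_cutout()].
#' @param thresholds A [channel_thresholds()].
#' @param plane Optional plane index recorded in the result.
#' @param half_width Band half-width recorded in the result, um.
#' @return An object of class `membrane_band` with fields `plane`,
#'   `half_width` and `counts` (named vector: `ampar_total`, `synaptic`,
#'   `extrasynaptic`).
#' @export
classify_band_puncta <- function(presynaptic, ampar, band, thresholds,
                                 plane = NA_integer_, half_width = 1) {
  if (!identical(dim(band), dim(ampar)) ||
      !identical(dim(presynaptic), dim(ampar)))
    stop("band mask and channel planes must share the same shape")
  pc <- plane_counts(presynaptic, ampar, thresholds, roi = band)
  counts <- c(ampar_total = unname(pc["ampar"]),
              synaptic = unname(pc["colocalized"]),
              extrasynaptic = unname(pc["ampar"] - pc["colocalized"]))
  structure(list(plane = plane, half_width = half_width, counts = counts),
            class = "membrane_band")
}

#' @export
print.membrane_band <- function(x, ...) {
  cat(sprintf(
    "membrane_band (plane %s, +/- %g um): ampar %g, synaptic %g, extrasynaptic %g\n",
    x$plane, x$half_width, x$counts[["ampar_total"]],
    x$counts[["synaptic"]], x$counts[["extrasynaptic"]]))
  invisible(x)
}

#' Full membrane optical-fraction analysis of one stack
#'
#' Convenience composition of the plasma-membrane workflow: pick the
#' peak-colocalization plane, trace the membrane (or accept a manual trace),
#' cut the 2-um band, and classify band AMPAR pixels as synaptic or
#' extrasynaptic.
#'
#' @param stack A [confocal_stack()].
#' @param thresholds A [channel_thresholds()].
#' @param centroid Soma centroid (row, col) in pixels; if missing, the
#'   brightest-presynaptic-region centroid of the peak plane is used via
#'   [detect_large_neurons()] with no size filter.
#' @param half_width Band half-width, um.
#' @param manual_trace Optional [membrane_trace()].
#' @param exclude Plane indices excluded from peak selection.
#' @return A `membrane_band` (see [classify_band_puncta()]) with the trace
#'   attached as attribute `trace`.
#' @export
membrane_fraction <- function(stack, thresholds, centroid = NULL,
                              half_width = 1, manual_trace = NULL,
                              exclude = integer()) {
  z <- select_peak_plane(stack, thresholds, exclude)
  pl <- get_plane(stack, z)
  if (is.null(centroid)) {
    cand <- detect_large_neurons(pl$presynaptic, thresholds,
                                 pixel_size = stack$pixel_size,
                                 min_diameter = 0)
    if (nrow(cand) == 0L) stop("no soma found on the peak plane")
    cand <- cand[which.max(cand$diameter_um), ]
    centroid <- c(cand$centroid_row, cand$centroid_col)
  }
  tr <- trace_membrane(pl$presynaptic, thresholds$presynaptic, centroid,
                       pixel_size = stack$pixel_size, manual = manual_trace)
  band <- band_cutout(tr, dim(pl$ampar), pixel_size = stack$pixel_size,
                      half_width = half_width)
  res <- classify_band_puncta(pl$presynaptic, pl$ampar, band, thresholds,
                              plane = z, half_width = half_width)
  attr(res, "trace") <- tr
  res
}
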