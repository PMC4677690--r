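#' Derive a channel threshold from control tissue
#'
#' Suprathreshold classification uses a predetermined pixel threshold based
#' on control tissue: the mean plus `k` standard deviations of all pixel
#' intensities in the requested channel of a control stack. Once derived, the
#' threshold is held constant across an experiment.
#'
#' @param control_stack A [confocal_stack()] imaged from control tissue.
#' @param channel `"presynaptic"` or `"ampar"`.
#' @param k Standard-deviation multiplier (default 2).
#' @return A single non-negative intensity threshold.
#' @export
derive_threshold <- function(control_stack, channel = c("presynaptic", "ampar"),
                             k = 2) {
  stopifnot(inherits(control_stack, "confocal_stack"))
  channel <- match.arg(channel)
  v <- as.numeric(control_stack[[channel]])
  if (length(v) == 0L) stop("control stack is empty")
  s <- stats::sd(v)
  if (is.na(s)) s <- 0       # single-pixel stack
  max(mean(v) + k * s, 0)
}

#' Channel threshold pair
#'
#' @param presynaptic,ampar Non-negative intensity thresholds.
#' @param derivation Optional list recording provenance (control stack id,
#'   `k` multiplier) for the run manifest.
#' @return An object of class `channel_thresholds`.
#' @export
channel_thresholds <- function(presynaptic, ampar, derivation = NULL) {
  stopifnot(presynaptic >= 0, ampar >= 0)
  structure(list(presynaptic = presynaptic, ampar = ampar,
                 derivation = derivation),
            class = "channel_thresholds")
}

#' Derive both channel thresholds from one control stack
#' @inheritParams derive_threshold
#' @param id Optional control-stack identifier recorded in the derivation.
#' @return A [channel_thresholds()].
#' @export
derive_thresholds <- function(control_stack, k = 2, id = NULL) {
  channel_thresholds(
    presynaptic = derive_threshold(control_stack, "presynaptic", k),
    ampar = derive_threshold(control_stack, "ampar", k),
    derivation = list(control_stack_id = id, k = k))
}

#' Suprathreshold and colocalized pixel counts for one optical plane
#'
#' A pixel is suprathreshold when it strictly exceeds its channel's
#' threshold; a pixel is colocalized (synaptic signal) when it is
#' suprathreshold in both channels simultaneously — the "yellow pixel"
#' overlap of the presynaptic marker and the AMPAR subunit.
#'
#' @param presynaptic,ampar Numeric matrices of one optical plane.
#' @param thresholds A [channel_thresholds()].
#' @param roi Optional logical matrix restricting counting to a region of
#'   interest; must match the plane shape.
#' @return Named numeric vector: `ampar`, `presynaptic`, `colocalized`
#'   pixel counts.
#' @export
plane_counts <- function(presynaptic, ampar, thresholds, roi = NULL) {
  stopifnot(inherits(thresholds, "channel_thresholds"))
  if (!identical(dim(presynaptic), dim(ampar)))
    stop("channel planes must share the same shape")
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(ampar)))
      stop("roi must match the plane shape")
    roi <- as.logical(roi)
  } else roi <- TRUE
  pre_hit <- (presynaptic > thresholds$presynaptic) & roi
  amp_hit <- (ampar > thresholds$ampar) & roi
  c(ampar = sum(amp_hit), presynaptic = sum(pre_hit),
    colocalized = sum(amp_hit & pre_hit))
}

#' Per-plane and whole-stack puncta pixel counts
#'
#' Applies [plane_counts()] to every optical plane of a z-stack and totals
#' the tallies, giving the amount of total AMPAR signal and of synaptic
#' (colocalized) signal through the stack.
#'
#' @param stack A [confocal_stack()].
#' @param thresholds A [channel_thresholds()].
#' @param roi Optional logical matrix (applied to every plane) or 3-D array.
#' @return An object of class `puncta_counts`: data frame `per_plane` with
#'   columns `plane`, `ampar`, `presynaptic`, `colocalized`, plus a named
#'   `totals` vector.
#' @export
stack_counts <- function(stack, thresholds, roi = NULL) {
  stopifnot(inherits(stack, "confocal_stack"))
  nz <- n_planes(stack)
  roi_plane <- function(z) {
    if (is.null(roi)) NULL
    else if (is.matrix(roi)) roi
    else roi[z, , ]
  }
  per <- t(vapply(seq_len(nz), function(z)
    plane_counts(stack$presynaptic[z, , ], stack$ampar[z, , ], thresholds,
                 roi_plane(z)),
    numeric(3L)))
  per_plane <- data.frame(plane = seq_len(nz), per)
  structure(list(per_plane = per_plane, totals = colSums(per)),
            class = "puncta_counts")
}

#' @export
print.puncta_counts <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "puncta_counts: %d plane(s); totals: ampar %g, presynaptic %g, colocalized %g\n",
    nrow(x$per_plane), t[["ampar"]], t[["presynaptic"]], t[["colocalized"]]))
  invisible(x)
}

#' Write puncta counts for one cell to CSV
#'
#' One row per optical plane plus a trailing `total` row, matching the
#' per-cell quantification record kept for each imaged neuron.
#'
#' @param counts A [stack_counts()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "puncta_counts"))
  tab <- counts$per_plane
  tab$plane <- as.character(tab$plane)
  tab <- rbind(tab, c(plane = "total", as.list(counts$totals)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Detect large ring-outlined neurons in a plane or projection
#'
#' Large motor neurons are identified by the distinctive presynaptic
#' (synaptophysin) outline surrounding the plasma membrane: the
#' suprathreshold presynaptic mask is morphologically closed, holes are
#' filled, connected regions are labelled, and candidates whose equivalent
#' diameter exceeds `min_diameter` are returned.
#'
#' @param image Presynaptic-channel matrix (one plane or a max projection).
#' @param thresholds A [channel_thresholds()] (presynaptic threshold used).
#' @param pixel_size um per pixel.
#' @param min_diameter Minimum equivalent cell-body diameter, um (default 40).
#' @param close_radius Structuring-element radius for morphological closing,
#'   um; bridges small gaps in the membrane ring.
#' @param window_id Optional sampling-window id recorded on each candidate.
#' @return Data frame of candidates: `window_id`, centroid
#'   (`centroid_row`, `centroid_col`, pixels), `diameter_um`, and
#'   `ring_score` (fraction of the filled region's perimeter that is
#'   suprathreshold in the presynaptic channel). Possibly zero rows.
#' @export
detect_large_neurons <- function(image, thresholds, pixel_size,
                                 min_diameter = 40, close_radius = 0.5,
                                 window_id = NA_integer_) {
  stopifnot(is.matrix(image), inherits(thresholds, "channel_thresholds"),
            pixel_size > 0)
  mask <- image > thresholds$presynaptic
  empty <- data.frame(window_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), diameter_um = numeric(),
                      ring_score = numeric())
  if (!any(mask)) return(empty)
  brush_px <- max(3L, 2L * as.integer(round(close_radius / pixel_size)) + 1L)
  m <- EBImage::Image(mask * 1)
  m <- EBImage::closing(m, EBImage::makeBrush(brush_px, shape = "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  labmat <- EBImage::imageData(lab)
  nlab <- max(labmat)
  if (nlab == 0) return(empty)
  out <- empty
  for (l in seq_len(nlab)) {
    region <- labmat == l
    area <- sum(region)
    diam <- 2 * sqrt(area / pi) * pixel_size
    if (diam <= min_diameter) next
    idx <- which(region, arr.ind = TRUE)
    per <- region_perimeter(region)
    score <- if (sum(per) > 0) mean(mask[per]) else 0
    out <- rbind(out, data.frame(
      window_id = window_id,
      centroid_row = mean(idx[, 1L]), centroid_col = mean(idx[, 2L]),
      diameter_um = diam, ring_score = score))
  }
  out
}

# Boundary pixels of a logical region (4-connectivity erosion complement).
region_perimeter <- function(region) {
  d <- dim(region)
  pad <- matrix(FALSE, d[1L] + 2L, d[2L] + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- region
  core <- pad[2:(d[1L] + 1L), 2:(d[2L] + 1L)] &
    pad[1:d[1L], 2:(d[2L] + 1L)] & pad[3:(d[1L] + 2L), 2:(d[2L] + 1L)] &
    pad[2:(d[1L] + 1L), 1:d[2L]] & pad[2:(d[1L] + 1L), 3:(d[2L] + 2L)]
  region & !core
}
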