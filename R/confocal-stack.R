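#' Two-channel confocal z-stack
#'
#' A `confocal_stack` bundles the two fluorescence channels of a confocal
#' acquisition (presynaptic marker, e.g. synaptophysin, and an AMPAR subunit,
#' e.g. GluA1 or GluA2) with the physical calibration needed to convert pixel
#' measurements to micrometres.
#'
#' @param presynaptic,ampar Non-negative numeric 3-D arrays indexed
#'   `(plane, row, col)`. Both channels must share the same dimensions.
#' @param pixel_size Lateral calibration, um per pixel.
#' @param z_interval Axial spacing between optical planes, um. The
#'   default 0.25 um matches standard spinning-disk sampling of large somata.
#'
#' @return An object of class `confocal_stack`: a list with elements
#'   `presynaptic`, `ampar`, `pixel_size`, `z_interval`.
#' @export
confocal_stack <- function(presynaptic, ampar, pixel_size = 0.1,
                           z_interval = 0.25) {
  presynaptic <- as_stack_array(presynaptic)
  ampar <- as_stack_array(ampar)
  if (!identical(dim(presynaptic), dim(ampar)))
    stop("channels must share identical dimensions")
  if (any(presynaptic < 0) || any(ampar < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar")
  if (!is.numeric(z_interval) || length(z_interval) != 1L || z_interval <= 0)
    stop("z_interval must be a positive scalar")
  structure(
    list(presynaptic = presynaptic, ampar = ampar,
         pixel_size = pixel_size, z_interval = z_interval),
    class = "confocal_stack"
  )
}

# Coerce a matrix (single plane) or 3-D array to (plane, row, col) layout.
as_stack_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("channel must be a matrix or 3-D array (plane, row, col)")
  storage.mode(x) <- "double"
  x
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$ampar)
  cat(sprintf(
    "confocal_stack: %d plane(s) of %d x %d px (%.3g um/px, dz = %.3g um)\n",
    d[1L], d[2L], d[3L], x$pixel_size, x$z_interval))
  invisible(x)
}

#' @export
dim.confocal_stack <- function(x) dim(x$ampar)

#' Number of optical planes in a stack
#' @param stack A [confocal_stack()].
#' @return Integer plane count.
#' @export
n_planes <- function(stack) dim(stack$ampar)[1L]

#' Extract one two-channel optical plane
#' @param stack A [confocal_stack()].
#' @param plane 1-based plane index.
#' @return List with matrices `presynaptic` and `ampar`.
#' @export
get_plane <- function(stack, plane) {
  stopifnot(plane >= 1L, plane <= n_planes(stack))
  list(presynaptic = stack$presynaptic[plane, , ],
       ampar = stack$ampar[plane, , ])
}

#' Write / read a confocal stack as multi-page TIFF plus JSON sidecar
#'
#' Each channel is written as its own multi-page 32-bit float TIFF; pixel
#' size and z-interval go to a JSON sidecar so a stack round-trips with its
#' calibration.
#'
#' @param stack A [confocal_stack()].
#' @param path Base path without extension; files `<path>_presynaptic.tif`,
#'   `<path>_ampar.tif` and `<path>.json` are created.
#' @return `write_stack`: the base path, invisibly. `read_stack`: a
#'   [confocal_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "confocal_stack"))
  nz <- n_planes(stack)
  peak <- max(stack$presynaptic, stack$ampar, 1)
  for (ch in c("presynaptic", "ampar")) {
    pages <- lapply(seq_len(nz), function(z) stack[[ch]][z, , ] / peak)
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", path, ch),
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(
    list(pixel_size = stack$pixel_size, z_interval = stack$z_interval,
         intensity_scale = peak),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  read_ch <- function(ch) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", path, ch), all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1L]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * meta$intensity_scale
    arr
  }
  confocal_stack(read_ch("presynaptic"), read_ch("ampar"),
                 pixel_size = meta$pixel_size, z_interval = meta$z_interval)
}
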