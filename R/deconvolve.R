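#' Gaussian point-spread-function kernel
#'
#' Builds a separable 3-D Gaussian PSF sampled at the stack's pixel/z pitch
#' and normalized to unit sum, truncated at 4 sigma.
#'
#' @param sigma_xy,sigma_z Lateral and axial PSF widths, um.
#' @param pixel_size,z_interval Sampling pitch, um.
#' @return A 3-D array `(plane, row, col)` with odd dimensions, summing to 1.
#' @export
gaussian_psf <- function(sigma_xy, sigma_z, pixel_size = 0.1,
                         z_interval = 0.25) {
  stopifnot(sigma_xy >= 0, sigma_z >= 0)
  ax <- function(sigma, pitch) {
    h <- max(1L, ceiling(4 * sigma / pitch))
    g <- exp(-(seq(-h, h) * pitch)^2 / (2 * max(sigma, 1e-12)^2))
    if (sigma == 0) g <- as.numeric(seq(-h, h) == 0)
    g
  }
  gx <- ax(sigma_xy, pixel_size)
  gz <- ax(sigma_z, z_interval)
  psf <- outer(gz, outer(gx, gx))
  psf / sum(psf)
}

# Circular 3-D convolution via FFT; psf is centred and wrapped to the array
# grid so a delta kernel is the identity.
fft_convolve <- function(arr, psf) {
  d <- dim(arr)
  pd <- dim(psf)
  if (any(pd > d)) {            # crop an oversized kernel centrally
    keep <- function(n, m) {
      if (n <= m) return(seq_len(n))
      c0 <- (n + 1L) %/% 2L
      h <- (m - 1L) %/% 2L
      (c0 - h):(c0 - h + m - 1L)
    }
    psf <- psf[keep(pd[1L], d[1L]), keep(pd[2L], d[2L]), keep(pd[3L], d[3L]),
               drop = FALSE]
    psf <- psf / sum(psf)
    pd <- dim(psf)
  }
  big <- array(0, d)
  big[seq_len(pd[1L]), seq_len(pd[2L]), seq_len(pd[3L])] <- psf
  centre <- (pd - 1L) / 2
  for (k in 1:3) {
    idx <- (seq_len(d[k]) - 1L + centre[k]) %% d[k] + 1L
    big <- switch(k, big[idx, , , drop = FALSE], big[, idx, , drop = FALSE],
                  big[, , idx, drop = FALSE])
  }
  out <- Re(stats::fft(stats::fft(arr) * stats::fft(big), inverse = TRUE)) /
    prod(d)
  out
}

#' Richardson-Lucy deconvolution of a confocal stack
#'
#' Iterative maximum-likelihood deblurring with a fixed, known PSF, applied
#' independently to both channels. Used to correct the diffusion of light
#' before puncta counting; iteration counts are held per target (e.g. 4 for
#' GluA1, 2 for GluA2) and constant across an experiment.
#'
#' @param stack A [confocal_stack()].
#' @param psf 3-D kernel with positive sum (normalized internally), e.g. from
#'   [gaussian_psf()].
#' @param iterations Non-negative iteration count; 0 returns the input
#'   unchanged.
#' @return A deconvolved [confocal_stack()]; intensities stay non-negative.
#' @export
deconvolve <- function(stack, psf, iterations) {
  stopifnot(inherits(stack, "confocal_stack"))
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 0)
    stop("iterations must be a non-negative count")
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(stack)
  s <- sum(psf)
  if (!is.finite(s) || s <= 0) stop("psf must have a positive finite sum")
  psf <- psf / s
  flipped <- psf[rev(seq_len(dim(psf)[1L])), rev(seq_len(dim(psf)[2L])),
                 rev(seq_len(dim(psf)[3L])), drop = FALSE]
  rl <- function(obs) {
    est <- pmax(obs, 1e-12)
    for (i in seq_len(iterations)) {
      blurred <- pmax(fft_convolve(est, psf), 1e-12)
      est <- est * fft_convolve(obs / blurred, flipped)
      est <- pmax(est, 0)
    }
    est
  }
  confocal_stack(rl(stack$presynaptic), rl(stack$ampar),
                 pixel_size = stack$pixel_size, z_interval = stack$z_interval)
}
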