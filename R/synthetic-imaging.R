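#' Simulate a ground-truth puncta field around a ringed soma
#'
#' Places a large motor-neuron soma (a circular membrane ring outlined by
#' presynaptic signal, as synaptophysin outlines real somata) in a square
#' field and populates it with labelled puncta:
#'
#' * `synaptic` AMPAR puncta sit on the membrane trace, each paired with a
#'   presynaptic punctum within `coloc_radius`;
#' * `extrasynaptic` AMPAR puncta sit inside the membrane band (within
#'   `band_half_width` of the trace) but at least `coloc_radius` away from
#'   every presynaptic punctum;
#' * `neuropil` puncta (both channels) are uniform outside the soma.
#'
#' This is the ground truth consumed by [generate_confocal_stack()]; it is
#' exact, i.e. recorded before any optical blurring or noise.
#'
#' @param field_um Side of the square field, um.
#' @param depth_um Axial extent of the stack, um.
#' @param soma_diameter Soma diameter, um; large ventral-horn motor neurons
#'   exceed 40 um.
#' @param n_ampar_puncta Number of membrane-associated AMPAR puncta.
#' @param synaptic_fraction Probability that a membrane AMPAR punctum is
#'   synaptic (colocalized with the presynaptic marker).
#' @param n_neuropil_puncta Number of neuropil puncta per channel.
#' @param coloc_radius Colocalization radius, um: a synaptic punctum's
#'   presynaptic partner lies within this distance.
#' @param band_half_width Half-width of the membrane band used to place
#'   extrasynaptic puncta, um.
#' @param seed Integer seed.
#' @return An object of class `imaging_ground_truth`: soma centre/diameter,
#'   closed `membrane_trace` polyline (um), a `puncta` data frame
#'   (x, y, z um, `channel`, `label`), the per-plane label count table for a
#'   given z-interval, and the generation parameters.
#' @export
simulate_puncta_field <- function(field_um = 60, depth_um = 4,
                                  soma_diameter = 45,
                                  n_ampar_puncta = 40,
                                  synaptic_fraction = 0.6,
                                  n_neuropil_puncta = 30,
                                  coloc_radius = 0.1,
                                  band_half_width = 1.0,
                                  seed = 1L) {
  if (synaptic_fraction < 0 || synaptic_fraction > 1)
    stop("synaptic_fraction must lie in [0, 1]")
  if (soma_diameter <= 0) stop("soma_diameter must be positive")
  if (soma_diameter + 2 * band_half_width >= field_um)
    stop(sprintf(
      "soma of %g um does not fit a %g um field (band included): enlarge the field",
      soma_diameter, field_um))
  set.seed(seed)
  centre <- c(field_um, field_um) / 2
  r <- soma_diameter / 2
  theta <- seq(0, 2 * pi, length.out = 181L)
  trace <- cbind(x = centre[1L] + r * cos(theta),
                 y = centre[2L] + r * sin(theta))
  z_mid <- depth_um / 2

  n_syn <- if (n_ampar_puncta > 0)
    stats::rbinom(1L, n_ampar_puncta, synaptic_fraction) else 0L
  n_extra <- n_ampar_puncta - n_syn

  rows <- list()
  # synaptic AMPAR puncta on the trace, each with a presynaptic partner
  if (n_syn > 0) {
    ang <- stats::runif(n_syn, 0, 2 * pi)
    px <- centre[1L] + r * cos(ang)
    py <- centre[2L] + r * sin(ang)
    pz <- z_mid + stats::runif(n_syn, -0.2, 0.2) * depth_um
    jit <- function(n) stats::runif(n, -coloc_radius / 2, coloc_radius / 2)
    rows$syn_a <- data.frame(x = px, y = py, z = pz,
                             channel = "ampar", label = "synaptic")
    rows$syn_p <- data.frame(x = px + jit(n_syn), y = py + jit(n_syn), z = pz,
                             channel = "presynaptic", label = "synaptic")
  }
  # extrasynaptic AMPAR puncta: inside the band, away from presynaptic puncta
  if (n_extra > 0) {
    ex <- matrix(NA_real_, 0L, 3L)
    presyn_xy <- if (n_syn > 0) cbind(rows$syn_p$x, rows$syn_p$y)
      else matrix(numeric(), 0L, 2L)
    while (nrow(ex) < n_extra) {
      ang <- stats::runif(n_extra, 0, 2 * pi)
      rad <- r + stats::runif(n_extra, -band_half_width, band_half_width)
      cand <- cbind(centre[1L] + rad * cos(ang), centre[2L] + rad * sin(ang))
      ok <- if (nrow(presyn_xy) > 0) {
        apply(cand, 1L, function(p)
          min(sqrt((presyn_xy[, 1L] - p[1L])^2 +
                   (presyn_xy[, 2L] - p[2L])^2)) >= coloc_radius)
      } else rep(TRUE, nrow(cand))
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) > 0)
        ex <- rbind(ex, cbind(cand,
                              z_mid + stats::runif(nrow(cand), -0.2, 0.2) * depth_um))
    }
    ex <- ex[seq_len(n_extra), , drop = FALSE]
    rows$extra <- data.frame(x = ex[, 1L], y = ex[, 2L], z = ex[, 3L],
                             channel = "ampar", label = "extrasynaptic")
  }
  # neuropil puncta, uniform outside the soma, both channels
  if (n_neuropil_puncta > 0) {
    np <- matrix(NA_real_, 0L, 2L)
    while (nrow(np) < 2L * n_neuropil_puncta) {
      cand <- cbind(stats::runif(2L * n_neuropil_puncta, 0, field_um),
                    stats::runif(2L * n_neuropil_puncta, 0, field_um))
      d <- sqrt((cand[, 1L] - centre[1L])^2 + (cand[, 2L] - centre[2L])^2)
      np <- rbind(np, cand[d > r + band_half_width, , drop = FALSE])
    }
    np <- np[seq_len(2L * n_neuropil_puncta), , drop = FALSE]
    ch <- rep(c("ampar", "presynaptic"), each = n_neuropil_puncta)
    rows$np <- data.frame(x = np[, 1L], y = np[, 2L],
                          z = stats::runif(2L * n_neuropil_puncta, 0, depth_um),
                          channel = ch, label = "neuropil")
  }
  puncta <- if (length(rows) > 0)
    do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  else data.frame(x = numeric(), y = numeric(), z = numeric(),
                  channel = character(), label = character())
  structure(
    list(soma_center = centre, soma_diameter = soma_diameter,
         membrane_trace = trace, puncta = puncta,
         field_um = field_um, depth_um = depth_um,
         synaptic_fraction = synaptic_fraction,
         coloc_radius = coloc_radius, band_half_width = band_half_width,
         seed = seed),
    class = "imaging_ground_truth"
  )
}

#' @export
print.imaging_ground_truth <- function(x, ...) {
  tab <- table(x$puncta$label[x$puncta$channel == "ampar"])
  cat(sprintf(
    "imaging_ground_truth: soma %g um in %g um field; AMPAR puncta: %s\n",
    x$soma_diameter, x$field_um,
    paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-plane ground-truth label counts
#'
#' Assigns each punctum to its nearest optical plane and tallies labels, so
#' plane-wise pipeline outputs can be checked against conserved totals.
#'
#' @param truth An [simulate_puncta_field()] result.
#' @param z_interval Plane spacing, um.
#' @return Data frame with one row per (plane, channel, label) and a count.
#' @export
plane_label_counts <- function(truth, z_interval = 0.25) {
  nz <- max(1L, ceiling(truth$depth_um / z_interval))
  p <- truth$puncta
  plane <- pmin(pmax(round(p$z / z_interval) + 1L, 1L), nz)
  as.data.frame(table(plane = factor(plane, levels = seq_len(nz)),
                      channel = p$channel, label = p$label),
                responseName = "count")
}

#' Generate a synthetic two-channel confocal stack with known ground truth
#'
#' Renders a [simulate_puncta_field()] scene to a confocal z-stack: the
#' membrane ring and every punctum become 3-D Gaussian spots, the result is
#' convolved with a Gaussian point-spread function, and Poisson shot noise
#' plus Gaussian read noise are added. The returned ground truth is exact
#' (recorded before blurring and noise).
#'
#' @param n_neurons Number of somata to place (laid out on a row; each gets
#'   its own field-width slot). The default single neuron matches the one
#'   neuron imaged per sampling window.
#' @param field_um,depth_um,soma_diameter,n_ampar_puncta,synaptic_fraction,n_neuropil_puncta,coloc_radius
#'   Passed to [simulate_puncta_field()].
#' @param pixel_size Lateral sampling, um/px.
#' @param z_interval Axial sampling, um.
#' @param spot_sigma_xy,spot_sigma_z Gaussian spot size of a rendered punctum
#'   (um); defaults 0.15 and 0.4.
#' @param spot_amplitude Peak intensity of a rendered punctum, photons.
#' @param ring_amplitude Peak intensity of the membrane ring, photons.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF widths (um); set both to 0 to
#'   skip optical blurring.
#' @param shot_noise Logical: add Poisson shot noise.
#' @param read_noise_sd Gaussian read-noise standard deviation (intensity
#'   units); 0 disables it.
#' @param background Constant background offset added before shot noise.
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return List with `stack` (a [confocal_stack()]) and `truth` (an
#'   `imaging_ground_truth`, one per neuron in a list when `n_neurons > 1`).
#' @export
generate_confocal_stack <- function(n_neurons = 1L, field_um = 60,
                                    depth_um = 4, soma_diameter = 45,
                                    n_ampar_puncta = 40,
                                    synaptic_fraction = 0.6,
                                    n_neuropil_puncta = 30,
                                    coloc_radius = 0.1,
                                    pixel_size = 0.1, z_interval = 0.25,
                                    spot_sigma_xy = 0.15, spot_sigma_z = 0.4,
                                    spot_amplitude = 100,
                                    ring_amplitude = 60,
                                    psf_sigma_xy = 0.2, psf_sigma_z = 0.5,
                                    shot_noise = TRUE, read_noise_sd = 2,
                                    background = 5, seed = 1L) {
  stopifnot(n_neurons >= 1L)
  set.seed(seed)
  truths <- lapply(seq_len(n_neurons), function(i)
    simulate_puncta_field(field_um = field_um, depth_um = depth_um,
                          soma_diameter = soma_diameter,
                          n_ampar_puncta = n_ampar_puncta,
                          synaptic_fraction = synaptic_fraction,
                          n_neuropil_puncta = n_neuropil_puncta,
                          coloc_radius = coloc_radius,
                          seed = sample.int(.Machine$integer.max, 1L)))
  npx <- as.integer(round(field_um / pixel_size))
  nz <- max(1L, as.integer(ceiling(depth_um / z_interval)))
  width <- npx * n_neurons

  pre <- array(0, c(nz, npx, width))
  amp <- array(0, c(nz, npx, width))
  for (i in seq_len(n_neurons)) {
    tr <- truths[[i]]
    off_x <- (i - 1L) * field_um
    # membrane ring rendered as densely sampled spots along the trace
    ring <- dense_polyline(tr$membrane_trace, step = pixel_size / 2)
    pre <- render_spots(pre, ring[, 1L] + off_x, ring[, 2L],
                        rep(depth_um / 2, nrow(ring)),
                        amplitude = ring_amplitude * pixel_size / 2 / spot_sigma_xy,
                        spot_sigma_xy, spot_sigma_z, pixel_size, z_interval)
    p <- tr$puncta
    for (ch in c("presynaptic", "ampar")) {
      sel <- p$channel == ch
      if (!any(sel)) next
      target <- if (ch == "presynaptic") "pre" else "amp"
      arr <- render_spots(get(target), p$x[sel] + off_x, p$y[sel], p$z[sel],
                          amplitude = spot_amplitude,
                          spot_sigma_xy, spot_sigma_z, pixel_size, z_interval)
      assign(target, arr)
    }
  }
  if (psf_sigma_xy > 0 || psf_sigma_z > 0) {
    psf <- gaussian_psf(psf_sigma_xy, psf_sigma_z, pixel_size, z_interval)
    pre <- fft_convolve(pre, psf)
    amp <- fft_convolve(amp, psf)
  }
  pre <- pre + background
  amp <- amp + background
  if (shot_noise) {
    pre[] <- stats::rpois(length(pre), pmax(pre, 0))
    amp[] <- stats::rpois(length(amp), pmax(amp, 0))
  }
  if (read_noise_sd > 0) {
    pre <- pre + stats::rnorm(length(pre), 0, read_noise_sd)
    amp <- amp + stats::rnorm(length(amp), 0, read_noise_sd)
  }
  pre <- pmax(pre, 0)
  amp <- pmax(amp, 0)
  stack <- confocal_stack(pre, amp, pixel_size = pixel_size,
                          z_interval = z_interval)
  list(stack = stack,
       truth = if (n_neurons == 1L) truths[[1L]] else truths)
}

# Resample a polyline at roughly uniform arc-length steps (um).
dense_polyline <- function(poly, step) {
  if (!isTRUE(all.equal(poly[1L, ], poly[nrow(poly), ], check.attributes = FALSE)))
    poly <- rbind(poly, poly[1L, ])
  out <- list()
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- cbind(a[1L] + t * (b[1L] - a[1L]), a[2L] + t * (b[2L] - a[2L]))
  }
  do.call(rbind, out)
}

# Add 3-D Gaussian spots at physical positions (um) into arr (plane,row,col).
# x maps to columns, y to rows, z to planes; pixel centres at (index-0.5)*pitch.
render_spots <- function(arr, x, y, z, amplitude, sigma_xy, sigma_z,
                         pixel_size, z_interval) {
  d <- dim(arr)
  hw <- ceiling(4 * sigma_xy / pixel_size)
  hz <- ceiling(4 * sigma_z / z_interval)
  amplitude <- rep_len(amplitude, length(x))
  for (k in seq_along(x)) {
    cx <- x[k] / pixel_size + 0.5
    cy <- y[k] / pixel_size + 0.5
    cz <- z[k] / z_interval + 0.5
    cols <- max(1L, floor(cx - hw)):min(d[3L], ceiling(cx + hw))
    rows <- max(1L, floor(cy - hw)):min(d[2L], ceiling(cy + hw))
    zs <- max(1L, floor(cz - hz)):min(d[1L], ceiling(cz + hz))
    if (!length(cols) || !length(rows) || !length(zs)) next
    gx <- exp(-((cols - cx) * pixel_size)^2 / (2 * sigma_xy^2))
    gy <- exp(-((rows - cy) * pixel_size)^2 / (2 * sigma_xy^2))
    gz <- exp(-((zs - cz) * z_interval)^2 / (2 * sigma_z^2))
    spot <- outer(gz, outer(gy, gx)) * amplitude[k]
    arr[zs, rows, cols] <- arr[zs, rows, cols] + spot
  }
  arr
}
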