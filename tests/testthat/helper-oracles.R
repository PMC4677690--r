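# Independent brute-force oracles used across the suite. Each is written as
# the dumbest correct computation (loops, per-pixel checks) so it cannot
# share a bug with the vectorized implementation it checks.

# Per-pixel double loop over one plane: suprathreshold and colocalized counts.
oracle_plane_counts <- function(pre, amp, th_pre, th_amp) {
  a <- p <- co <- 0L
  for (i in seq_len(nrow(amp))) {
    for (j in seq_len(ncol(amp))) {
      hit_a <- amp[i, j] > th_amp
      hit_p <- pre[i, j] > th_pre
      if (hit_a) a <- a + 1L
      if (hit_p) p <- p + 1L
      if (hit_a && hit_p) co <- co + 1L
    }
  }
  c(ampar = a, presynaptic = p, colocalized = co)
}

# Mann-Whitney U of x by counting pairwise wins plus half-ties.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1
    else if (xi == yj) u <- u + 0.5
  }
  u
}

# Interaction F from explicit design matrices and normal equations:
# full model vs the same model without the interaction columns.
oracle_interaction_f <- function(y, covariate, a, b) {
  a <- factor(a); b <- factor(b)
  dummy <- function(f) {
    lev <- levels(f)
    sapply(lev[-1L], function(l) as.numeric(f == l))
  }
  Xa <- dummy(a); Xb <- dummy(b)
  Xab <- matrix(0, length(y), 0)
  for (i in seq_len(ncol(Xa))) for (j in seq_len(ncol(Xb)))
    Xab <- cbind(Xab, Xa[, i] * Xb[, j])
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  X_red <- cbind(1, covariate, Xa, Xb)
  X_full <- cbind(X_red, Xab)
  q <- ncol(Xab)
  df2 <- length(y) - ncol(X_full)
  ((rss(X_red) - rss(X_full)) / q) / (rss(X_full) / df2)
}

# Direct dense rendering of Gaussian spots (no truncation): intensity of
# every voxel as an explicit sum over puncta.
oracle_render <- function(puncta_xyz, amplitude, dims, pixel_size, z_interval,
                          sigma_xy, sigma_z) {
  arr <- array(0, dims)
  for (z in seq_len(dims[1L])) for (r in seq_len(dims[2L])) for (cc in seq_len(dims[3L])) {
    xz <- (z - 0.5) * z_interval
    xy <- (r - 0.5) * pixel_size
    xx <- (cc - 0.5) * pixel_size
    v <- 0
    for (k in seq_len(nrow(puncta_xyz))) {
      v <- v + amplitude * exp(
        -((xx - puncta_xyz[k, 1L])^2 + (xy - puncta_xyz[k, 2L])^2) /
          (2 * sigma_xy^2) -
          (xz - puncta_xyz[k, 3L])^2 / (2 * sigma_z^2))
    }
    arr[z, r, cc] <- v
  }
  arr
}

# Millisecond-resolution state integration of a behavioral event log.
oracle_session_bins <- function(events, session_s) {
  dt <- 0.001
  n <- as.integer(session_s / dt)
  tt <- (seq_len(n) - 0.5) * dt
  in_solution <- rep(TRUE, n)
  state <- TRUE
  bounds <- c(events$time_s, Inf)
  states <- c(as.character(events$state), NA)
  k <- 1L
  for (i in seq_len(n)) {
    while (tt[i] >= bounds[k]) {
      state <- states[k] == "down"
      k <- k + 1L
    }
    in_solution[i] <- state
  }
  n_bins <- as.integer(ceiling(session_s / 60))
  bin <- pmin(floor(tt / 60) + 1L, n_bins)
  time_in <- vapply(seq_len(n_bins), function(b) sum(in_solution[bin == b]) * dt,
                    numeric(1L))
  lifts <- events$time_s[events$state == "up"]
  resp <- vapply(seq_len(n_bins), function(b)
    sum(lifts >= (b - 1) * 60 & lifts < b * 60), numeric(1L))
  list(time_in = time_in, resp = resp)
}

# Small deterministic two-channel stack for count tests.
toy_stack <- function(nz = 3L, n = 8L, seed = 1L) {
  set.seed(seed)
  confocal_stack(array(runif(nz * n * n, 0, 10), c(nz, n, n)),
                 array(runif(nz * n * n, 0, 10), c(nz, n, n)),
                 pixel_size = 0.1, z_interval = 0.25)
}

# Fast noise-free single-soma stack used by several membrane tests.
clean_stack <- function(synaptic_fraction = 0.6, seed = 1L,
                        n_ampar = 30L, n_neuropil = 10L) {
  generate_confocal_stack(
    field_um = 36, depth_um = 2, soma_diameter = 26,
    n_ampar_puncta = n_ampar, synaptic_fraction = synaptic_fraction,
    n_neuropil_puncta = n_neuropil, pixel_size = 0.2,
    psf_sigma_xy = 0, psf_sigma_z = 0, shot_noise = FALSE,
    read_noise_sd = 0, background = 0, seed = seed)
}
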