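test_that("peak-plane selection is an argmax with lowest-index ties", {
  th <- channel_thresholds(5, 5)
  one <- toy_stack(nz = 1, seed = 1)
  expect_equal(select_peak_plane(one, th), 1L)
  # colocalization planted only on plane 7
  pre <- array(0, c(10, 6, 6)); amp <- array(0, c(10, 6, 6))
  pre[7, 2:4, 2:4] <- 10; amp[7, 2:4, 2:4] <- 10
  st <- confocal_stack(pre, amp)
  expect_equal(select_peak_plane(st, th), 7L)
  # ties break toward the lowest plane index
  pre[3, 2:4, 2:4] <- 10; amp[3, 2:4, 2:4] <- 10
  expect_equal(select_peak_plane(confocal_stack(pre, amp), th), 3L)
  # brute-force argmax agreement on random stacks
  for (seed in 1:10) {
    st <- toy_stack(nz = 6, seed = seed)
    counts <- vapply(1:6, function(z)
      oracle_plane_counts(st$presynaptic[z, , ], st$ampar[z, , ], 5, 5)[["colocalized"]],
      numeric(1))
    expect_equal(select_peak_plane(st, th), which.max(counts))
  }
})

test_that("peak-plane selection is permutation-consistent and honours exclusions", {
  th <- channel_thresholds(5, 5)
  st <- toy_stack(nz = 6, seed = 11)
  z0 <- select_peak_plane(st, th)
  perm <- c(4, 6, 1, 3, 2, 5)
  stp <- confocal_stack(st$presynaptic[perm, , ], st$ampar[perm, , ])
  expect_equal(perm[select_peak_plane(stp, th)], z0)
  z2 <- select_peak_plane(st, th, exclude = z0)
  expect_true(z2 != z0)
  expect_error(select_peak_plane(st, th, exclude = 1:6), "excluded")
})

test_that("membrane tracing recovers a planted circle within a pixel", {
  px <- 0.2
  n <- 200
  xy <- (seq_len(n) - 0.5) * px
  dist_c <- sqrt(outer((xy - 20)^2, (xy - 20)^2, "+"))
  plane <- ifelse(abs(dist_c - 12) < 0.4, 100, 0)
  tr <- trace_membrane(plane, 10, centroid = c(100, 100), pixel_size = px)
  expect_s3_class(tr, "membrane_trace")
  expect_equal(tr$source, "auto")
  r_px <- sqrt((tr$vertices[, 1] - 100.5)^2 + (tr$vertices[, 2] - 100.5)^2)
  expect_true(all(abs(r_px * px - 12) < 3 * px))
  # threshold above all intensities -> tracing error
  expect_error(trace_membrane(plane, 1000, c(100, 100), px), "trace")
  # centroid outside any contour -> error
  expect_error(trace_membrane(plane, 10, c(5, 5), px), "centroid")
  # manual trace passes through unchanged
  man <- membrane_trace(cbind(c(1, 5, 5), c(1, 1, 5)), source = "manual")
  expect_identical(trace_membrane(plane, 10, c(100, 100), manual = man), man)
})

test_that("band cutout has the stated 2-um geometry", {
  # horizontal line trace across a 41 x 41 image, 0.1 um pixels
  tr <- membrane_trace(cbind(c(1, 21, 41), c(21, 21, 21)))
  band <- band_cutout(tr, c(41, 41), pixel_size = 0.1, half_width = 1,
                      closed = FALSE)
  # 21 pixels wide: centre row +/- 10
  expect_true(all(band[11:31, 21]))
  expect_false(any(band[c(1:10, 32:41), 21]))
  expect_equal(sum(band[, 21]), 21)
  # shrinking the half-width approaches the rasterized trace
  thin <- band_cutout(tr, c(41, 41), pixel_size = 0.1, half_width = 1e-6,
                      closed = FALSE)
  expect_equal(which(thin[, 21]), 21L)
})

test_that("band cutout matches a brute-force distance oracle and grows with half-width", {
  set.seed(21)
  verts <- cbind(sample(5:25, 6), sample(5:25, 6))
  tr <- membrane_trace(verts)
  shape <- c(30, 30)
  px <- 0.2
  prev <- matrix(FALSE, shape[1], shape[2])
  for (hw in c(0.4, 0.8, 1.2)) {
    band <- band_cutout(tr, shape, pixel_size = px, half_width = hw)
    # oracle: per-pixel minimum distance over all closed-polyline segments
    vv <- rbind(verts, verts[1, ])
    for (r in seq_len(shape[1])) for (cc in seq_len(shape[2])) {
      dmin <- Inf
      for (s in seq_len(nrow(vv) - 1)) {
        a <- vv[s, ]; b <- vv[s + 1, ]
        ab <- b - a
        t <- sum((c(cc, r) - a) * ab) / sum(ab^2)
        t <- min(max(t, 0), 1)
        dmin <- min(dmin, sqrt(sum((c(cc, r) - (a + t * ab))^2)))
      }
      expect_equal(band[r, cc], dmin * px <= hw)
    }
    expect_true(all(band[prev]))    # monotone growth
    prev <- band
  }
})

test_that("band puncta classification splits synaptic from extrasynaptic", {
  th <- channel_thresholds(5, 5)
  band <- matrix(TRUE, 6, 6)
  none <- matrix(0, 6, 6)
  r0 <- classify_band_puncta(none, none, band, th)
  expect_equal(unname(r0$counts), c(0, 0, 0))
  # every band AMPAR pixel presynaptic-positive -> extrasynaptic 0
  sig <- matrix(10, 6, 6)
  r1 <- classify_band_puncta(sig, sig, band, th)
  expect_equal(r1$counts[["extrasynaptic"]], 0)
  expect_equal(r1$counts[["synaptic"]], 36)
  # counts respect the band mask
  half <- band; half[, 4:6] <- FALSE
  r2 <- classify_band_puncta(sig, sig, half, th)
  expect_equal(r2$counts[["ampar_total"]], 18)
  expect_error(classify_band_puncta(sig, sig, matrix(TRUE, 2, 2), th), "shape")
})

test_that("planted 12:8 synaptic/extrasynaptic puncta are recovered on a clean neuron", {
  sim <- clean_stack(synaptic_fraction = 0, seed = 30, n_ampar = 0,
                     n_neuropil = 0)
  # deterministic puncta layout: 12 on the trace with presynaptic partners,
  # 8 in the band away from them
  truth <- sim$truth
  ang_s <- seq(0, 2 * pi, length.out = 13)[-13]
  ang_e <- ang_s[1:8] + pi / 12
  r <- truth$soma_diameter / 2
  ctr <- truth$soma_center
  z <- 1
  syn <- cbind(ctr[1] + r * cos(ang_s), ctr[2] + r * sin(ang_s), z)
  ext <- cbind(ctr[1] + (r - 0.7) * cos(ang_e), ctr[2] + (r - 0.7) * sin(ang_e), z)
  amp <- punctaquant:::render_spots(array(0, dim(sim$stack$ampar)),
    c(syn[, 1], ext[, 1]), c(syn[, 2], ext[, 2]), c(syn[, 3], ext[, 3]),
    100, 0.15, 0.4, 0.2, 0.25)
  pre <- punctaquant:::render_spots(array(0, dim(sim$stack$ampar)),
    syn[, 1], syn[, 2], syn[, 3], 100, 0.15, 0.4, 0.2, 0.25)
  st <- confocal_stack(pre, amp, pixel_size = 0.2, z_interval = 0.25)
  th <- channel_thresholds(20, 20)
  zsel <- select_peak_plane(st, th)
  pl <- get_plane(st, zsel)
  tr <- membrane_trace(cbind(truth$membrane_trace[, 1] / 0.2 + 0.5,
                             truth$membrane_trace[, 2] / 0.2 + 0.5))
  band <- band_cutout(tr, dim(pl$ampar), pixel_size = 0.2, half_width = 1)
  res <- classify_band_puncta(pl$presynaptic, pl$ampar, band, th, plane = zsel)
  # punctum-wise oracle: count planted spots whose rendered centre pixel is
  # synaptic (presynaptic-positive) vs not
  got_ratio <- res$counts[["synaptic"]] / res$counts[["extrasynaptic"]]
  expect_equal(got_ratio, 12 / 8, tolerance = 0.25)
  # pixel counts are conserved
  expect_equal(res$counts[["ampar_total"]],
               res$counts[["synaptic"]] + res$counts[["extrasynaptic"]])
})

test_that("estimated synaptic fraction tracks the planted fraction across neurons", {
  fractions <- seq(0.05, 0.95, length.out = 10)
  est <- planted <- numeric(0)
  for (i in seq_along(fractions)) {
    sim <- generate_confocal_stack(
      field_um = 36, depth_um = 2, soma_diameter = 26,
      n_ampar_puncta = 40, synaptic_fraction = fractions[i],
      n_neuropil_puncta = 10, pixel_size = 0.2, ring_amplitude = 30,
      seed = 300 + i)
    ctrl <- generate_confocal_stack(
      field_um = 36, depth_um = 2, soma_diameter = 26, n_ampar_puncta = 0,
      n_neuropil_puncta = 0, ring_amplitude = 0, pixel_size = 0.2,
      seed = 999)$stack
    th <- derive_thresholds(ctrl)
    ctr_px <- sim$truth$soma_center / 0.2 + 0.5
    mb <- membrane_fraction(sim$stack, th,
                            centroid = c(ctr_px[2], ctr_px[1]))
    amp_lbl <- sim$truth$puncta$label[sim$truth$puncta$channel == "ampar"]
    planted[i] <- mean(amp_lbl[amp_lbl != "neuropil"] == "synaptic")
    est[i] <- mb$counts[["synaptic"]] / mb$counts[["ampar_total"]]
  }
  expect_gte(stats::cor(est, planted, method = "spearman"), 0.9)
})
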