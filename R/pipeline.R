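#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run (simulate -> quantify ->
#' membrane fraction -> statistics) into a serializable list, so a manifest
#' plus the seed reproduces the run exactly.
#'
#' @param seed Global integer seed; per-stage child seeds are derived from it
#'   (see [derive_seed()]).
#' @param n_cells_per_group Synthetic neurons per stimulation group per
#'   target.
#' @param targets Named list per AMPAR subunit target; each element carries
#'   `iterations` (Richardson-Lucy iteration count) and the planted synaptic
#'   fractions `fraction_control` and `fraction_stimulated`. Defaults plant
#'   synaptic GluA1 up and synaptic GluA2 down in stimulated tissue.
#' @param threshold_k Control-tissue threshold multiplier.
#' @param band_half_width Membrane band half-width, um.
#' @param pixel_size,field_um,depth_um,soma_diameter,n_ampar_puncta,n_neuropil_puncta
#'   Imaging geometry forwarded to [generate_confocal_stack()].
#' @param psf_sigma_xy,psf_sigma_z PSF used both to blur simulated stacks and
#'   as the known kernel for deconvolution.
#' @param alpha Significance level for the statistics stage.
#' @param output_dir Where result tables and the manifest are written; NULL
#'   keeps everything in memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cells_per_group = 20L,
                            targets = list(
                              GluA1 = list(iterations = 4L,
                                           fraction_control = 0.35,
                                           fraction_stimulated = 0.65),
                              GluA2 = list(iterations = 2L,
                                           fraction_control = 0.65,
                                           fraction_stimulated = 0.35)),
                            threshold_k = 2, band_half_width = 1,
                            pixel_size = 0.2, field_um = 56, depth_um = 2.5,
                            soma_diameter = 45, n_ampar_puncta = 60,
                            n_neuropil_puncta = 20,
                            psf_sigma_xy = 0.2, psf_sigma_z = 0.5,
                            alpha = 0.05, output_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_cells_per_group >= 0, threshold_k >= 0, band_half_width > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Derive a per-stage child seed from the global seed
#'
#' Child seeds are `(seed * 48271 + stage_offset) mod (2^31 - 1)` — a single
#' multiplicative-congruential step per stage — so stages can be rerun
#' independently yet remain fully determined by the global seed.
#'
#' @param seed Global seed.
#' @param offset Integer stage offset (each stage uses a distinct offset).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + offset) %% m + 1)
}

#' Run the full synthetic quantification pipeline
#'
#' Executes every stage on synthetic cohorts with known ground truth:
#'
#' 1. derive channel thresholds from a simulated control (background-only)
#'    stack;
#' 2. per target and stimulation group, simulate `n_cells_per_group` neurons
#'    with the configured planted synaptic fractions;
#' 3. deconvolve each stack (per-target iteration count), count neuropil and
#'    membrane-band pixels, and estimate each cell's synaptic fraction;
#' 4. compare stimulated vs control synaptic counts per target (Student's t
#'    and Mann-Whitney U).
#'
#' Cells are keyed by anonymized ids in the per-cell table; the id-to-group
#' key is a separate table, mirroring a blinded workflow.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `cells` (anonymized per-cell
#'   table), `key` (id to group/target), `stats` (per-target test table),
#'   `thresholds`, and `manifest`. When `config$output_dir` is set, the
#'   tables and manifest are also written there as CSV/JSON.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  control <- generate_confocal_stack(
    field_um = config$field_um, depth_um = config$depth_um,
    soma_diameter = config$soma_diameter,
    n_ampar_puncta = 0L, n_neuropil_puncta = 0L, ring_amplitude = 0,
    pixel_size = config$pixel_size,
    psf_sigma_xy = config$psf_sigma_xy, psf_sigma_z = config$psf_sigma_z,
    seed = derive_seed(config$seed, 1L))$stack
  thresholds <- derive_thresholds(control, k = config$threshold_k,
                                  id = "synthetic-control")
  psf <- gaussian_psf(config$psf_sigma_xy, config$psf_sigma_z,
                      config$pixel_size, control$z_interval)
  cells <- list()
  key <- list()
  cell_i <- 0L
  for (target in names(config$targets)) {
    tcfg <- config$targets[[target]]
    for (grp in c("control", "stimulated")) {
      frac <- if (grp == "control") tcfg$fraction_control
        else tcfg$fraction_stimulated
      for (j in seq_len(config$n_cells_per_group)) {
        cell_i <- cell_i + 1L
        cid <- sprintf("cell_%04d", cell_i)
        sim <- generate_confocal_stack(
          field_um = config$field_um, depth_um = config$depth_um,
          soma_diameter = config$soma_diameter,
          n_ampar_puncta = config$n_ampar_puncta,
          synaptic_fraction = frac,
          n_neuropil_puncta = config$n_neuropil_puncta,
          pixel_size = config$pixel_size,
          psf_sigma_xy = config$psf_sigma_xy,
          psf_sigma_z = config$psf_sigma_z,
          seed = derive_seed(config$seed, 100L * cell_i))
        st <- deconvolve(sim$stack, psf, tcfg$iterations)
        neuropil <- stack_counts(st, thresholds)
        ctr_px <- sim$truth$soma_center / config$pixel_size + 0.5
        band <- membrane_fraction(st, thresholds,
                                  centroid = c(ctr_px[2L], ctr_px[1L]),
                                  half_width = config$band_half_width)
        syn <- band$counts[["synaptic"]]
        tot <- band$counts[["ampar_total"]]
        cells[[cell_i]] <- data.frame(
          cell = cid, peak_plane = band$plane,
          neuropil_ampar = neuropil$totals[["ampar"]],
          neuropil_colocalized = neuropil$totals[["colocalized"]],
          band_ampar = tot, band_synaptic = syn,
          band_extrasynaptic = band$counts[["extrasynaptic"]],
          synaptic_fraction = if (tot > 0) syn / tot else NA_real_,
          planted_fraction = frac)
        key[[cell_i]] <- data.frame(cell = cid, target = target, group = grp)
      }
    }
  }
  cells <- do.call(rbind, cells)
  key <- do.call(rbind, key)
  stats_tab <- NULL
  if (is.null(cells) || nrow(key) == 0L) {
    warning("no cells simulated; statistics stage skipped")
    cells <- data.frame()
  } else {
    merged <- merge(cells, key, by = "cell")
    stats_tab <- do.call(rbind, lapply(names(config$targets), function(tg) {
      sub <- merged[merged$target == tg, ]
      x <- sub$band_synaptic[sub$group == "stimulated"]
      y <- sub$band_synaptic[sub$group == "control"]
      tt <- students_t(x, y)
      uu <- mann_whitney_u(x, y)
      data.frame(target = tg,
                 mean_stimulated = mean(x), mean_control = mean(y),
                 direction = ifelse(mean(x) > mean(y), "up", "down"),
                 t_statistic = tt$statistic, t_p = tt$p_value,
                 u_statistic = uu$statistic, u_p = uu$p_value)
    }))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("punctaquant")),
    seed = config$seed,
    thresholds = list(presynaptic = thresholds$presynaptic,
                      ampar = thresholds$ampar, k = config$threshold_k),
    config = unclass(config)[setdiff(names(config), "output_dir")])
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(config$output_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(key, file.path(config$output_dir, "group_key.csv"),
                     row.names = FALSE)
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(config$output_dir, "stats.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(cells = cells, key = key, stats = stats_tab,
                 thresholds = thresholds, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d cells\n", nrow(x$cells)))
  if (!is.null(x$stats)) {
    cat("stimulated vs control (band synaptic pixels):\n")
    print(x$stats, row.names = FALSE)
  }
  invisible(x)
}
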