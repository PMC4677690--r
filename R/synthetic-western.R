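#' Generate a synthetic quantitative Western dataset
#'
#' Emulates the measurement model of a pooled, replicated fluorescent Western
#' experiment: a 2 (stimulation) x T (time) factorial with a fixed number of
#' subjects per cell in each of several independent replications. The target
#' band intensity is the cell mean plus a loading-control covariate effect
#' plus Gaussian noise; loading control and background are drawn from stated
#' normal distributions (background truncated positive).
#'
#' @param cell_means Named numeric vector or matrix of target means, one per
#'   design cell; if a matrix, rows = stimulation levels, cols = time levels.
#' @param stimulation_levels,time_levels Factor levels (defaults
#'   `c("control", "INS")` and `c("20min", "2h", "24h")`).
#' @param n_per_cell Subjects per cell per replication (default 4).
#' @param n_replications Independent replications pooled for analysis
#'   (default 3).
#' @param sd Residual SD of the target intensity; must be positive.
#' @param covariate_slope Slope of the target on the centred loading control.
#' @param lc_mean,lc_sd Loading-control distribution (beta-actin).
#' @param bg_mean,bg_sd Background median pixel-density distribution.
#' @param replication_sd SD of additive replication (blot-run) offsets.
#' @param seed Integer seed.
#' @return Data frame of class `western_dataset` with columns `subject`,
#'   `stimulation`, `time`, `replication`, `target`, `loading_control`,
#'   `background_median`, `normalized` (target over background median).
#' @export
generate_western_dataset <- function(cell_means,
                                     stimulation_levels = c("control", "INS"),
                                     time_levels = c("20min", "2h", "24h"),
                                     n_per_cell = 4L, n_replications = 3L,
                                     sd = 1, covariate_slope = 0.5,
                                     lc_mean = 10, lc_sd = 1,
                                     bg_mean = 5, bg_sd = 0.5,
                                     replication_sd = 0, seed = 1L) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive")
  n_cells <- length(stimulation_levels) * length(time_levels)
  if (is.matrix(cell_means)) cell_means <- as.numeric(t(cell_means))
  if (length(cell_means) != n_cells)
    stop(sprintf("need one mean per design cell (%d)", n_cells))
  set.seed(seed)
  design <- expand.grid(time = time_levels, stimulation = stimulation_levels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("stimulation", "time")]
  design$cell_mean <- as.numeric(cell_means)
  rep_offset <- stats::rnorm(n_replications, 0, replication_sd)
  rows <- list()
  subj <- 0L
  for (r in seq_len(n_replications)) {
    for (i in seq_len(nrow(design))) {
      lc <- stats::rnorm(n_per_cell, lc_mean, lc_sd)
      bg <- pmax(stats::rnorm(n_per_cell, bg_mean, bg_sd), 0.1)
      target <- design$cell_mean[i] + rep_offset[r] +
        covariate_slope * (lc - lc_mean) + stats::rnorm(n_per_cell, 0, sd)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("s%03d", subj + seq_len(n_per_cell)),
        stimulation = design$stimulation[i], time = design$time[i],
        replication = sprintf("rep%d", r),
        target = target, loading_control = lc, background_median = bg)
      subj <- subj + n_per_cell
    }
  }
  out <- do.call(rbind, rows)
  out$target <- pmax(out$target, 0)
  out$normalized <- normalize_band(out$target, out$background_median)
  class(out) <- c("western_dataset", "data.frame")
  out
}

#' Generate a synthetic dilution calibration series
#'
#' Produces band fluorescence for a 1:2 dilution curve at several scanning
#' intensity settings. By default one setting is linear in protein amount and
#' the others saturate, mimicking an over-scanned membrane, so the linear
#' range can be recovered by [select_linear_setting()].
#'
#' @param settings Character vector of setting names.
#' @param linear_setting Which setting responds linearly.
#' @param gain Fluorescence per ug protein for the linear setting.
#' @param saturation Ceiling applied to the non-linear settings.
#' @param noise_sd Relative Gaussian noise SD (fraction of signal).
#' @param n_points,max_protein_ug Passed to [dilution_amounts()].
#' @param seed Integer seed.
#' @return Data frame with `setting`, `protein_ug`, `fluorescence`.
#' @export
generate_dilution_series <- function(settings = c("low", "medium", "high"),
                                     linear_setting = "medium",
                                     gain = 50, saturation = 400,
                                     noise_sd = 0.02, n_points = 6,
                                     max_protein_ug = 20, seed = 1L) {
  stopifnot(linear_setting %in% settings, noise_sd >= 0)
  set.seed(seed)
  amounts <- dilution_amounts(max_protein_ug, n_points)$protein_ug
  gains <- stats::setNames(
    gain * 2^(seq_along(settings) - match(linear_setting, settings)),
    settings)
  rows <- lapply(settings, function(s) {
    f <- gains[[s]] * amounts
    if (s != linear_setting) f <- pmin(f, saturation)  # flat-topped response
    f <- f * (1 + stats::rnorm(length(f), 0, noise_sd))
    data.frame(setting = s, protein_ug = amounts, fluorescence = pmax(f, 0))
  })
  do.call(rbind, rows)
}
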