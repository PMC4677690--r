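#' Background-normalize a Western band intensity
#'
#' Quantitative fluorescent Western intensities are expressed relative to the
#' median pixel density of background fluorescence on the membrane.
#'
#' @param band_intensity Band fluorescence (vectorized).
#' @param background_median Median background pixel density; must be > 0.
#' @return `band_intensity / background_median`.
#' @export
normalize_band <- function(band_intensity, background_median) {
  if (any(background_median <= 0))
    stop("background median must be positive")
  band_intensity / background_median
}

#' Select the scanning intensity in the linear range of a dilution curve
#'
#' For each scanning-intensity setting, fits ordinary least squares of band
#' fluorescence on total protein loaded and reports R-squared; the setting
#' whose fluorescence is most linearly related to protein concentration is
#' selected. Calibration curves should achieve R-squared above ~0.98 before
#' an antibody is used for quantification.
#'
#' @param series Data frame with columns `setting`, `protein_ug`,
#'   `fluorescence` (a 1:2 dilution series per setting, >= 3 points each;
#'   settings with fewer points are skipped with a warning).
#' @return List with `best_setting` and a data frame `r_squared`
#'   (`setting`, `r_squared`, `n_points`).
#' @export
select_linear_setting <- function(series) {
  need <- c("setting", "protein_ug", "fluorescence")
  if (!all(need %in% names(series)))
    stop("series needs columns: ", paste(need, collapse = ", "))
  settings <- unique(series$setting)
  if (length(settings) < 2L) stop("need at least 2 scanning settings")
  rows <- lapply(settings, function(s) {
    sub <- series[series$setting == s, ]
    if (nrow(sub) < 3L) {
      warning(sprintf("setting '%s' has < 3 points; skipped", s))
      return(NULL)
    }
    r2 <- if (stats::var(sub$fluorescence) == 0) 0 else
      suppressWarnings(    # exactly linear series trip the perfect-fit notice
        summary(stats::lm(fluorescence ~ protein_ug, data = sub)))$r.squared
    data.frame(setting = s, r_squared = r2, n_points = nrow(sub))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no setting has enough dilution points to assess linearity")
  list(best_setting = tab$setting[which.max(tab$r_squared)], r_squared = tab)
}

#' Build a 1:2 dilution series table
#'
#' @param max_protein_ug Protein loaded in the most concentrated lane, ug.
#' @param n_points Number of dilution points (>= 4).
#' @param dilution Dilution factor between successive lanes (default 2).
#' @return Data frame with `protein_ug` strictly decreasing by the factor.
#' @export
dilution_amounts <- function(max_protein_ug = 20, n_points = 6,
                             dilution = 2) {
  stopifnot(n_points >= 4L, dilution > 1, max_protein_ug > 0)
  data.frame(protein_ug = max_protein_ug / dilution^(seq_len(n_points) - 1L))
}
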