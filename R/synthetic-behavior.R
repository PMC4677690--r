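#' Generate a synthetic behavioral cohort with exponential acquisition
#'
#' Emulates group dynamics in the spinal sensorimotor task: per-bin response
#' duration follows a noisy exponential approach to an asymptote,
#' `d[i+1] = d[i] + alpha * (asymptote - d[i]) + noise`, clipped to
#' \[0, 60\] s. Subjects that learn (e.g. a drug-treated group) use
#' `alpha > 0`; non-learners (vehicle) use `alpha = 0` and stay near their
#' starting duration.
#'
#' @param n_subjects Subjects in the cohort.
#' @param group Group label (e.g. `"vehicle"`, `"naspm"`).
#' @param n_bins 1-min bins per session (default 30).
#' @param alpha Acquisition rate in \[0, 1\]; 0 = no learning.
#' @param asymptote Asymptotic response duration, s, in \[0, 60\].
#' @param start Response duration in bin 1, s.
#' @param noise_sd Per-bin Gaussian noise SD, s.
#' @param seed Integer seed.
#' @return List of `behavior_session` objects (one per subject), each with
#'   per-bin `response_duration`; `time_in_solution` and `response_number`
#'   are back-filled consistently with the response-duration equation
#'   assuming zero lifts per bin.
#' @export
generate_behavior_cohort <- function(n_subjects = 10L, group = "vehicle",
                                     n_bins = 30L, alpha = 0,
                                     asymptote = 40, start = 0,
                                     noise_sd = 2, seed = 1L) {
  stopifnot(n_bins >= 1L, alpha >= 0, alpha <= 1,
            asymptote >= 0, asymptote <= 60, noise_sd >= 0)
  set.seed(seed)
  lapply(seq_len(n_subjects), function(k) {
    d <- numeric(n_bins)
    d[1L] <- min(max(start + stats::rnorm(1L, 0, noise_sd), 0), 60)
    if (n_bins > 1L) for (i in seq_len(n_bins - 1L)) {
      d[i + 1L] <- d[i] + alpha * (asymptote - d[i]) +
        stats::rnorm(1L, 0, noise_sd)
      d[i + 1L] <- min(max(d[i + 1L], 0), 60)
    }
    # back-fill raw measures: with zero lifts, duration = 60 - time_in_solution,
    # which stays consistent over the full [0, 60] s range
    resp <- rep(0, n_bins)
    time_in <- 60 - d
    structure(list(
      subject = sprintf("%s_%02d", group, k), group = group,
      bins = data.frame(bin = seq_len(n_bins), time_in_solution = time_in,
                        response_number = resp, response_duration = d)),
      class = "behavior_session")
  })
}
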