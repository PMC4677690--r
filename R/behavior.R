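#' Generate an intermittent nociceptive stimulation schedule
#'
#' Pulses of fixed duration are delivered over a session on a variable
#' interstimulus interval: the first pulse starts at t = 0 and subsequent
#' onsets are appended, each a uniformly drawn ISI after the previous onset,
#' for as long as the pulse still ends within the session. At the defaults
#' (6-min session, 80-ms pulses, ISI uniform on 0.2-3.8 s, mean 2 s) this
#' yields about 180 stimulation presentations.
#'
#' @param session_s Session length, s (default 360).
#' @param isi_range Length-2 ISI range, s (default `c(0.2, 3.8)`); onsets are
#'   spaced onset-to-onset by these draws.
#' @param pulse_ms Pulse duration, ms (default 80); must not exceed the
#'   minimum ISI.
#' @param seed Integer seed.
#' @return An object of class `stim_schedule`: `onsets` (s), `isis` (s),
#'   `pulse_ms`, `session_s`, `isi_range`.
#' @export
generate_schedule <- function(session_s = 360, isi_range = c(0.2, 3.8),
                              pulse_ms = 80, seed = 1L) {
  stopifnot(length(isi_range) == 2L, isi_range[1L] > 0,
            isi_range[1L] <= isi_range[2L], session_s > 0)
  pulse_s <- pulse_ms / 1000
  if (pulse_s > isi_range[1L])
    stop("pulse duration exceeds the minimum interstimulus interval")
  set.seed(seed)
  onsets <- 0
  repeat {
    isi <- stats::runif(1L, isi_range[1L], isi_range[2L])
    nxt <- onsets[length(onsets)] + isi
    if (nxt + pulse_s > session_s) break
    onsets <- c(onsets, nxt)
  }
  structure(list(onsets = onsets, isis = diff(onsets), pulse_ms = pulse_ms,
                 session_s = session_s, isi_range = isi_range),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "stim_schedule: %d pulses of %g ms over %g s (mean ISI %.2f s)\n",
    length(x$onsets), x$pulse_ms, x$session_s, mean(x$isis)))
  invisible(x)
}

#' Write schedule onsets as CSV
#' @param schedule A [generate_schedule()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(onset_s = schedule$onsets), path,
                   row.names = FALSE)
  invisible(path)
}

#' Response duration for one behavioral time bin
#'
#' The spinal instrumental learning metric combines how long the contact
#' electrode stayed in the salt solution and how many flexion responses
#' occurred in a 1-min bin:
#' `(60 - time_in_solution) / (response_number + 1)` seconds.
#'
#' @param time_in_solution Seconds in solution during the bin, in \[0, 60\].
#' @param response_number Number of electrode lifts in the bin, >= 0.
#' @return Response duration in seconds, in \[0, 60\]. Vectorized.
#' @export
response_duration <- function(time_in_solution, response_number) {
  if (any(time_in_solution < 0 | time_in_solution > 60))
    stop("time_in_solution must lie in [0, 60] s")
  if (any(response_number < 0))
    stop("response_number must be non-negative")
  (60 - time_in_solution) / (response_number + 1)
}

#' Summarize a contact-electrode event log into per-bin learning metrics
#'
#' Integrates the electrode's in-solution time within each 1-min bin, counts
#' lifts (a lift counts in the bin where it began), and derives response
#' durations. The session starts with the electrode in solution; events
#' alternate `up`, `down`, `up`, ...
#'
#' @param events Data frame with columns `time_s` (non-decreasing) and
#'   `state` (`"up"` = lifted out of solution, `"down"` = returned).
#' @param session_s Session length, s (default 1800 = 30 one-minute bins).
#' @param subject,group Identifiers recorded on the session.
#' @return An object of class `behavior_session`: `subject`, `group`, and a
#'   data frame `bins` with `bin`, `time_in_solution`, `response_number`,
#'   `response_duration`.
#' @export
summarize_session <- function(events, session_s = 1800,
                              subject = NA_character_,
                              group = NA_character_) {
  stopifnot(all(c("time_s", "state") %in% names(events)))
  t <- events$time_s
  s <- as.character(events$state)
  if (is.unsorted(t)) stop("event timestamps must be non-decreasing")
  if (any(t < 0 | t > session_s)) stop("event outside the session")
  expected <- rep(c("up", "down"), length.out = length(s))
  if (length(s) > 0 && !all(s == expected))
    stop("events must alternate up/down starting with 'up'")
  n_bins <- as.integer(ceiling(session_s / 60))
  # in-solution intervals: [0, up1], [down1, up2], ..., [last down, end]
  starts <- c(0, t[s == "down"])
  ends <- c(t[s == "up"], session_s)
  ends <- ends[seq_along(starts)]
  time_in <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * 60
    hi <- min(b * 60, session_s)
    time_in[b] <- sum(pmax(0, pmin(ends, hi) - pmax(starts, lo)))
  }
  lifts <- t[s == "up"]
  resp <- vapply(seq_len(n_bins), function(b)
    sum(lifts >= (b - 1) * 60 & lifts < b * 60), numeric(1L))
  # a lift exactly at session end belongs to the last bin
  resp[n_bins] <- resp[n_bins] + sum(lifts == session_s)
  bins <- data.frame(
    bin = seq_len(n_bins), time_in_solution = time_in,
    response_number = resp,
    response_duration = response_duration(pmin(time_in, 60), resp))
  structure(list(subject = subject, group = group, bins = bins),
            class = "behavior_session")
}

#' @export
print.behavior_session <- function(x, ...) {
  cat(sprintf(
    "behavior_session '%s' (%s): %d bins, mean response duration %.2f s\n",
    x$subject, x$group, nrow(x$bins), mean(x$bins$response_duration)))
  invisible(x)
}

#' Write per-bin behavioral metrics as CSV
#' @param session A [summarize_session()] or generated `behavior_session`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  tab <- cbind(subject = session$subject, group = session$group,
               session$bins)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
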