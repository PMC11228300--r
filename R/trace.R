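# Zone-occupancy trial traces: an event stream of (entry time, zone)
# pairs over a stated trial duration, the abstraction of a tracking
# export. "none" marks time outside every scored zone.

#' Construct a trial trace from an event stream
#'
#' @param t_s numeric entry timestamps (seconds), strictly increasing,
#'   first at >= 0, all < `duration`.
#' @param zone character zone labels, one per event; consecutive events
#'   must have distinct zones. Each event's zone is occupied until the
#'   next event (or trial end).
#' @param duration trial duration in seconds.
#' @param trial_id optional identifier.
#' @return data.frame of class `trial_trace` with columns `t_s`, `zone`
#'   and attributes `duration`, `trial_id`.
#' @export
trial_trace <- function(t_s, zone, duration, trial_id = "trial") {
  stopifnot(length(t_s) == length(zone), duration > 0)
  if (length(t_s) == 0) stop("a trace needs at least one event")
  if (any(diff(t_s) <= 0)) stop("event timestamps must be strictly increasing")
  if (t_s[1] < 0 || t_s[length(t_s)] >= duration)
    stop("timestamps must lie in [0, duration)")
  zone <- as.character(zone)
  if (length(zone) > 1 && any(zone[-1] == zone[-length(zone)]))
    stop("consecutive events must have distinct zones")
  structure(data.frame(t_s = t_s, zone = zone, stringsAsFactors = FALSE),
            duration = duration, trial_id = trial_id,
            class = c("trial_trace", "data.frame"))
}

#' Simulate a zone-occupancy trial
#'
#' Generates an alternating-renewal event stream: the animal alternates
#' between a "none" state and interaction zones, with exponentially
#' distributed sojourns whose means are set so that the realized
#' zone-time fractions converge to `occupancy_profile` as the trial grows.
#' `bout_rate` is the expected number of interaction cycles per second
#' (mean cycle length `1/bout_rate`).
#'
#' @param duration trial duration, seconds (the assays here are 300 or
#'   600 s trials).
#' @param occupancy_profile named non-negative numeric vector of target
#'   zone-time fractions summing to <= 1; the remainder is time in no
#'   scored zone.
#' @param bout_rate interaction cycles per second, default 1/30.
#' @param seed integer seed.
#' @param zone_labels optional labels (default `names(occupancy_profile)`).
#' @param trial_id optional identifier.
#' @return A [trial_trace].
#' @examples
#' tr <- generate_trial_trace(300, c(mouse = 0.4, object = 0.2), seed = 1)
#' head(tr)
#' @export
generate_trial_trace <- function(duration, occupancy_profile,
                                 bout_rate = 1 / 30, seed = 1L,
                                 zone_labels = names(occupancy_profile),
                                 trial_id = "trial") {
  stopifnot(duration > 0, bout_rate > 0)
  if (is.null(zone_labels) || any(!nzchar(zone_labels)))
    stop("occupancy_profile must be named (zone labels)")
  if (any(occupancy_profile < 0))
    stop("occupancy fractions must be non-negative")
  f_tot <- sum(occupancy_profile)
  if (f_tot > 1 + 1e-9)
    stop("occupancy fractions must sum to <= 1")
  names(occupancy_profile) <- zone_labels
  set.seed(seed)
  if (f_tot < 1e-12)
    return(trial_trace(0, "none", duration, trial_id))
  active <- occupancy_profile[occupancy_profile > 0]
  if (f_tot >= 1 - 1e-9 && length(active) == 1)
    return(trial_trace(0, names(active), duration, trial_id))
  q <- active / f_tot
  cycle <- 1 / bout_rate
  m_zone <- f_tot * cycle
  tt <- numeric(0); zz <- character(0)
  t <- 0
  if (f_tot >= 1 - 1e-9) {
    # no unscored time: alternate directly among zones, never repeating
    prev <- ""
    while (t < duration) {
      probs <- q
      if (nzchar(prev)) probs[prev] <- 0
      z <- sample(names(q), 1, prob = probs)
      tt <- c(tt, t); zz <- c(zz, z); prev <- z
      t <- t + stats::rexp(1, 1 / m_zone)
    }
  } else {
    m_none <- (1 - f_tot) * cycle
    while (t < duration) {
      tt <- c(tt, t); zz <- c(zz, "none")
      t <- t + stats::rexp(1, 1 / m_none)
      if (t >= duration) break
      z <- sample(names(q), 1, prob = q)
      tt <- c(tt, t); zz <- c(zz, z)
      t <- t + stats::rexp(1, 1 / m_zone)
    }
  }
  trial_trace(tt, zz, duration, trial_id)
}

#' Build a trial trace from per-frame tracking samples
#'
#' Tracking exports often give one zone label per video frame rather
#' than an event stream. This collapses consecutive identical samples
#' into zone-entry events; the trial duration is the sample count over
#' the frame rate unless given explicitly.
#'
#' @param zone character vector of per-frame zone labels, in frame
#'   order.
#' @param frame_rate frames per second.
#' @param duration optional trial duration in seconds.
#' @param trial_id optional identifier.
#' @return A [trial_trace].
#' @examples
#' trace_from_samples(c("none", "none", "A", "A", "A", "none"),
#'                    frame_rate = 2)
#' @export
trace_from_samples <- function(zone, frame_rate, duration = NULL,
                               trial_id = "trial") {
  stopifnot(length(zone) >= 1, frame_rate > 0)
  zone <- as.character(zone)
  if (is.null(duration)) duration <- length(zone) / frame_rate
  change <- c(TRUE, zone[-1] != zone[-length(zone)])
  trial_trace((which(change) - 1) / frame_rate, zone[change], duration,
              trial_id)
}

#' Write / read a trial trace as a CSV event log (`t_s,zone`)
#' @param trace a `trial_trace`.
#' @param path output path.
#' @return `path` invisibly (write) or a `trial_trace` (read).
#' @export
write_trial_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trial_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# duration=", attr(trace, "duration")), con)
  write.table(as.data.frame(trace), con, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_trace
#' @param duration trial duration; if `NULL`, read from the `# duration=`
#'   header line (error if absent).
#' @export
read_trial_trace <- function(path, duration = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# duration=", first)) {
    if (is.null(duration))
      duration <- as.numeric(sub("^# duration=", "", first))
    df <- read.table(path, header = TRUE, sep = ",", skip = 1,
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(duration))
      stop("duration not stated in file; pass `duration`")
    df <- read.table(path, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE)
  }
  trial_trace(df$t_s, df$zone, duration)
}
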