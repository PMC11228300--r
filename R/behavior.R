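# Behavioral indices from zone-occupancy traces: trial summaries,
# sociability / social-novelty preference, spontaneous alternation,
# elevated-plus-maze open-arm ratio, one-sample tests, bout metrics.

.trace_intervals <- function(trace) {
  stopifnot(inherits(trace, "trial_trace"))
  duration <- attr(trace, "duration")
  n <- nrow(trace)
  data.frame(zone = trace$zone,
             start = trace$t_s,
             end = c(trace$t_s[-1], duration),
             stringsAsFactors = FALSE)
}

#' Summarize a zone-occupancy trial
#'
#' Per zone: total occupancy time (summed inter-event intervals), entry
#' count (transitions into the zone), latency to first entry (`NA` =
#' never entered), longest single bout, and time-binned occupancy.
#'
#' @param trace a [trial_trace].
#' @param bin_width bin width in seconds for time-binned occupancy,
#'   default 60.
#' @param interaction_zones optional subset of zone labels designated as
#'   interaction zones (recorded in the result).
#' @return Object of class `trial_summary`: list with `zone_time`,
#'   `entries`, `latency`, `max_bout`, `binned` (bins x zones matrix of
#'   occupancy seconds), `duration`, `bin_width`, `interaction_zones`.
#' @examples
#' tr <- trial_trace(c(0, 10, 20), c("A", "B", "A"), 30)
#' summarize_trial(tr, bin_width = 15)$entries
#' @export
summarize_trial <- function(trace, bin_width = 60,
                            interaction_zones = NULL) {
  iv <- .trace_intervals(trace)
  duration <- attr(trace, "duration")
  zones <- unique(iv$zone)
  if (!is.null(interaction_zones)) {
    # zones never entered are legitimate: they get 0 time below
    zones <- union(zones, interaction_zones)
  }
  dur <- iv$end - iv$start
  zone_time <- vapply(zones, function(z) sum(dur[iv$zone == z]),
                      numeric(1))
  entries <- vapply(zones, function(z) sum(iv$zone == z), numeric(1))
  latency <- vapply(zones, function(z) {
    hit <- which(iv$zone == z)
    if (length(hit)) iv$start[hit[1]] else NA_real_
  }, numeric(1))
  max_bout <- vapply(zones, function(z) {
    d <- dur[iv$zone == z]
    if (length(d)) max(d) else 0
  }, numeric(1))
  breaks <- seq(0, duration, by = bin_width)
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)
  nb <- length(breaks) - 1
  binned <- matrix(0, nb, length(zones),
                   dimnames = list(paste0("bin", seq_len(nb)), zones))
  for (k in seq_len(nrow(iv))) {
    for (b in seq_len(nb)) {
      overlap <- min(iv$end[k], breaks[b + 1]) - max(iv$start[k], breaks[b])
      if (overlap > 0)
        binned[b, iv$zone[k]] <- binned[b, iv$zone[k]] + overlap
    }
  }
  structure(list(zone_time = zone_time, entries = entries,
                 latency = latency, max_bout = max_bout, binned = binned,
                 duration = duration, bin_width = bin_width,
                 interaction_zones = interaction_zones),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("Trial summary (", x$duration, " s):\n", sep = "")
  print(data.frame(zone = names(x$zone_time), time_s = x$zone_time,
                   entries = x$entries, latency_s = x$latency,
                   max_bout_s = x$max_bout, row.names = NULL))
  invisible(x)
}

.preference_index <- function(t_target, t_other, kind) {
  if (t_target < 0 || t_other < 0) stop("times must be non-negative")
  value <- if (t_target + t_other == 0) NA_real_ else
    (t_target - t_other) / (t_target + t_other)
  if (is.na(value))
    warning("both interaction times are zero; index undefined")
  structure(list(value = value, t_target = t_target, t_other = t_other,
                 kind = kind), class = "preference_index")
}

#' Sociability preference index
#'
#' `(T_mouse - T_object) / (T_mouse + T_object)`: time with the social
#' stimulus minus time with the object, over the combined interaction
#' time. Ranges over `[-1, 1]`; positive values mean social preference.
#'
#' @param t_mouse,t_object interaction times in seconds.
#' @return Object of class `preference_index` (`$value` holds the index;
#'   `NA` with a warning when both times are zero).
#' @export
sociability_index <- function(t_mouse, t_object)
  .preference_index(t_mouse, t_object, "sociability")

#' Social novelty preference index
#'
#' `(T_novel - T_familiar) / (T_novel + T_familiar)`: time with the novel
#' conspecific minus time with the familiar one, over the combined time.
#'
#' @param t_novel,t_familiar interaction times in seconds.
#' @return A `preference_index`.
#' @export
social_novelty_index <- function(t_novel, t_familiar)
  .preference_index(t_novel, t_familiar, "social_novelty")

#' @export
print.preference_index <- function(x, ...) {
  cat(sprintf("%s index: %.4f  (target %.1f s vs other %.1f s)\n",
              x$kind, x$value, x$t_target, x$t_other))
  invisible(x)
}

#' Familiarity preference across two trials
#'
#' Ratio of interaction time with the same stimulus animal in trial 1
#' over trial 2. Values near 1 mean no habituation (the natural null for
#' a one-sample test against 1); large values mean interaction collapsed
#' on re-exposure. This ratio interpretation is one reasonable reading
#' of a two-trial familiarity measure, and is labelled as such.
#'
#' @param t_trial1,t_trial2 interaction times in seconds; `t_trial2`
#'   must be positive.
#' @return Ratio `>= 0`; `NA` with a warning when `t_trial2` is zero.
#' @export
familiarity_preference <- function(t_trial1, t_trial2) {
  if (t_trial1 < 0 || t_trial2 < 0) stop("times must be non-negative")
  if (t_trial2 == 0) {
    warning("no trial-2 interaction time; ratio undefined")
    return(NA_real_)
  }
  t_trial1 / t_trial2
}

#' Spontaneous alternation percentage (Y-maze)
#'
#' An alternation is any window of three consecutive arm visits covering
#' all three arms. The percentage is `100 * alternations / (visits - 2)`,
#' the number of alternations over the total possible alternations.
#'
#' @param visit_sequence ordered character vector of arm labels; at least
#'   3 visits, consecutive visits must differ.
#' @return Percentage in `[0, 100]`; `NA` with a warning for fewer than
#'   3 visits.
#' @examples
#' alternation_percentage(c("A", "B", "C", "A", "B", "C"))  # 100
#' @export
alternation_percentage <- function(visit_sequence) {
  v <- as.character(visit_sequence)
  if (length(v) < 3) {
    warning("fewer than 3 arm visits; alternation undefined")
    return(NA_real_)
  }
  if (any(v[-1] == v[-length(v)]))
    stop("consecutive visits must enter different arms")
  if (length(unique(v)) > 3)
    stop("more than three distinct arm labels")
  w <- cbind(v[1:(length(v) - 2)], v[2:(length(v) - 1)], v[3:length(v)])
  alt <- apply(w, 1, function(r) length(unique(r)) == 3)
  100 * sum(alt) / (length(v) - 2)
}

#' Elevated-plus-maze open-arm time ratio
#'
#' Total time in the open arms divided by total time in the closed arms
#' (not open over total).
#'
#' @param t_open,t_closed times in seconds; `t_closed` must be positive.
#' @return Ratio `>= 0`; `NA` with a warning when `t_closed` is zero.
#' @export
open_arm_ratio <- function(t_open, t_closed) {
  if (t_open < 0 || t_closed < 0) stop("times must be non-negative")
  if (t_closed == 0) {
    warning("no closed-arm time; ratio undefined")
    return(NA_real_)
  }
  t_open / t_closed
}

#' One-sample t-test against a hypothetical mean
#'
#' Used to test preference indices against their null value (0 for the
#' signed indices, 1 for a familiarity-preference ratio). `df = n - 1`.
#'
#' @param values numeric vector, `n >= 2`, non-constant.
#' @param hypothetical_mean the null mean.
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_test <- function(values, hypothetical_mean = 0) {
  if (length(values) < 2) stop("need at least 2 observations")
  if (stats::var(values) == 0)
    stop("zero variance; one-sample t is undefined")
  ht <- stats::t.test(values, mu = hypothetical_mean)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Longest zone bout within a time window
#'
#' The longest contiguous occupancy of `zone`, clipped to `window`
#' (e.g. the first minute of a trial). Zero if the zone is never
#' occupied inside the window.
#'
#' @param trace a [trial_trace].
#' @param zone zone label.
#' @param window numeric length-2 `(start, end)` in seconds, within the
#'   trial.
#' @return Longest clipped bout, seconds.
#' @export
max_bout_in_window <- function(trace, zone, window = c(0, 60)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  duration <- attr(trace, "duration")
  if (window[1] < 0 || window[2] > duration)
    stop("window must lie within the trial")
  iv <- .trace_intervals(trace)
  iv <- iv[iv$zone == zone, , drop = FALSE]
  if (!nrow(iv)) return(0)
  clipped <- pmin(iv$end, window[2]) - pmax(iv$start, window[1])
  max(c(0, clipped))
}
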