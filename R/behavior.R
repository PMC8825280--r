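# Phenotyping-cage intake streams, two-bottle preference and optogenetic
# stimulation schedules.

#' Construct a cumulative intake stream
#'
#' Cage weight sensors report cumulative intake every 5 s, quantized to
#' 0.01 g. Raw streams may contain transient negative dips from sensor
#' noise; see [clean_intake()].
#'
#' @param timestamps Strictly increasing, uniformly spaced times (seconds).
#' @param cumulative_g Cumulative intake readings in grams (>= 0).
#' @param channel One of `"bottle_a"`, `"bottle_b"`, `"food"`.
#' @return An object of class `intake_stream`.
#' @export
intake_stream <- function(timestamps, cumulative_g,
                          channel = c("bottle_a", "bottle_b", "food")) {
  channel <- match.arg(channel)
  stopifnot(length(timestamps) == length(cumulative_g))
  if (length(timestamps) > 1L) {
    d <- diff(timestamps)
    if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9) {
      stop("timestamps must be strictly increasing and uniformly spaced",
           call. = FALSE)
    }
  }
  if (any(cumulative_g < 0)) stop("negative intake readings", call. = FALSE)
  structure(list(timestamps = as.numeric(timestamps),
                 cumulative_g = as.numeric(cumulative_g),
                 channel = channel),
            class = "intake_stream")
}

#' @export
print.intake_stream <- function(x, ...) {
  cat(sprintf("<intake_stream> %s: %d readings over %.1f min, final %.2f g\n",
              x$channel, length(x$timestamps),
              diff(range(x$timestamps)) / 60,
              utils::tail(x$cumulative_g, 1)))
  invisible(x)
}

#' Enforce monotone cumulative intake (carry-forward correction)
#'
#' Applies the cage-firmware correction rule literally: scanning left to
#' right, any reading lower than its (already corrected) predecessor is
#' replaced by that predecessor. The output is monotone non-decreasing, the
#' operation is idempotent, and no reading is ever decreased.
#'
#' @param raw An [intake_stream()] (or bare numeric vector of cumulative
#'   readings).
#' @return For a stream input, a list with `$stream` (cleaned
#'   `intake_stream`) and `$n_corrected` (number of replaced readings). For
#'   a numeric input, the corrected numeric vector.
#' @export
clean_intake <- function(raw) {
  correct <- function(v) {
    if (length(v) < 2L) return(v)
    for (i in 2L:length(v)) if (v[i] < v[i - 1L]) v[i] <- v[i - 1L]
    v
  }
  if (is.numeric(raw)) return(correct(raw))
  stopifnot(inherits(raw, "intake_stream"))
  fixed <- correct(raw$cumulative_g)
  out <- raw
  out$cumulative_g <- fixed
  list(stream = out, n_corrected = sum(fixed != raw$cumulative_g))
}

#' Construct a two-bottle choice session
#'
#' @param sucrose,sucralose [intake_stream()] objects for the two bottles
#'   (raw streams are cleaned on construction).
#' @param session_min Session length in minutes (default 60).
#' @return An object of class `choice_session` with cleaned streams and
#'   1-min binned intakes (`$binned`: data frame `minute`, `sucrose_g`,
#'   `sucralose_g`, cumulative since session start).
#' @export
choice_session <- function(sucrose, sucralose, session_min = 60) {
  stopifnot(inherits(sucrose, "intake_stream"),
            inherits(sucralose, "intake_stream"))
  suc <- clean_intake(sucrose)$stream
  scl <- clean_intake(sucralose)$stream
  bin1 <- function(s) {
    rel <- s$timestamps - s$timestamps[1L]
    mins <- seq_len(session_min)
    vapply(mins, function(m) {
      i <- max(which(rel <= m * 60))
      s$cumulative_g[i] - s$cumulative_g[1L]
    }, numeric(1))
  }
  structure(
    list(sucrose = suc, sucralose = scl, session_min = session_min,
         binned = data.frame(minute = seq_len(session_min),
                             sucrose_g = bin1(suc),
                             sucralose_g = bin1(scl))),
    class = "choice_session"
  )
}

#' Two-bottle sucrose preference
#'
#' Intakes are the cleaned cumulative readings at the end of the session
#' minus those at its start; preference is
#' `100 * sucrose / (sucrose + sucralose)`.
#'
#' @param session A [choice_session()].
#' @return An object of class `preference_result`: `$sucrose_g`,
#'   `$sucralose_g`, `$total_g`, `$preference_pct` (`NA` with a flag when
#'   nothing was consumed) and `$undefined`.
#' @export
compute_preference <- function(session) {
  stopifnot(inherits(session, "choice_session"))
  take <- function(s) {
    rel <- s$timestamps - s$timestamps[1L]
    i <- max(which(rel <= session$session_min * 60))
    s$cumulative_g[i] - s$cumulative_g[1L]
  }
  suc <- take(session$sucrose); scl <- take(session$sucralose)
  total <- suc + scl
  structure(
    list(sucrose_g = suc, sucralose_g = scl, total_g = total,
         preference_pct = if (total > 0) 100 * suc / total else NA_real_,
         undefined = total == 0),
    class = "preference_result"
  )
}

#' @export
print.preference_result <- function(x, ...) {
  if (x$undefined) {
    cat("<preference_result> no intake; preference undefined\n")
  } else {
    cat(sprintf(
      "<preference_result> sucrose %.2f g, sucralose %.2f g -> %.1f%% sucrose\n",
      x$sucrose_g, x$sucralose_g, x$preference_pct))
  }
  invisible(x)
}

#' Stable-preference criterion over repeated tests
#'
#' A stable sucrose preference is two consecutive tests both above 66% that
#' differ by no more than 15 percentage points.
#'
#' @param test_prefs Numeric vector of per-test preference percentages
#'   (length >= 2).
#' @return List with `$stable` and `$first_pair` (index of the first
#'   qualifying pair's first test, or `NA`).
#' @export
stable_preference <- function(test_prefs) {
  if (length(test_prefs) < 2L) stop("need at least two tests", call. = FALSE)
  for (i in seq_len(length(test_prefs) - 1L)) {
    a <- test_prefs[i]; b <- test_prefs[i + 1L]
    if (a > 66 && b > 66 && abs(a - b) <= 15) {
      return(list(stable = TRUE, first_pair = i))
    }
  }
  list(stable = FALSE, first_pair = NA_integer_)
}

#' Periodic optogenetic stimulation schedule
#'
#' Cyclic laser schedule: `on_min` minutes on followed by `off_min` minutes
#' off, repeating over the session; sessions begin with the laser on by
#' default. Within on-intervals, pulses run at `freq_hz` with the given duty
#' fraction (20% duty at 40 Hz is a 5-ms pulse).
#'
#' @param duration_min Session length in minutes (default 60).
#' @param on_min,off_min On/off cycle components in minutes (defaults 1/2).
#' @param freq_hz Pulse frequency (default 40 Hz).
#' @param duty Duty fraction in `(0, 1]` (default 0.2).
#' @param amplitude_v Pulse amplitude in volts (default 5).
#' @param start_on Begin with an on-interval (default `TRUE`).
#' @return An object of class `stim_schedule` with `$intervals` (data frame
#'   `on_start`, `on_end` in seconds), `$pulse_width_s`, `$total_on_s` and
#'   pulse parameters. `trigger = "periodic"`.
#' @export
periodic_schedule <- function(duration_min = 60, on_min = 1, off_min = 2,
                              freq_hz = 40, duty = 0.2, amplitude_v = 5,
                              start_on = TRUE) {
  if (on_min + off_min <= 0) stop("cycle length must be positive", call. = FALSE)
  if (duty <= 0 || duty > 1) stop("duty must lie in (0, 1]", call. = FALSE)
  dur_s <- duration_min * 60; on_s <- on_min * 60; off_s <- off_min * 60
  period <- on_s + off_s
  first_on <- if (start_on) 0 else off_s
  starts <- seq(first_on, dur_s, by = period)
  starts <- starts[starts < dur_s]
  ends <- pmin(starts + on_s, dur_s)
  structure(
    list(intervals = data.frame(on_start = starts, on_end = ends),
         pulse_width_s = duty / freq_hz,
         total_on_s = sum(ends - starts),
         freq_hz = freq_hz, duty = duty, amplitude_v = amplitude_v,
         trigger = "periodic"),
    class = "stim_schedule"
  )
}

#' Intake-triggered stimulation schedule
#'
#' Every `trigger_g` of consumed liquid triggers `stim_s` seconds of laser
#' stimulation starting at the tick where the increment was recorded.
#' Triggers landing inside an active interval are merged into a single
#' extended interval (the stimulation hardware cannot double-fire); the
#' total trigger count still reflects every quantum consumed.
#'
#' @param stream A cleaned [intake_stream()].
#' @param trigger_g Intake quantum per trigger in grams (default 0.01).
#' @param stim_s Stimulation bout length in seconds (default 5).
#' @param freq_hz,duty,amplitude_v Pulse parameters as in
#'   [periodic_schedule()].
#' @return A `stim_schedule` (`trigger = "intake"`) with merged
#'   `$intervals`, `$n_triggers = floor(total intake / trigger_g)`,
#'   `$pulse_width_s` and `$total_on_s`.
#' @export
intake_triggered_schedule <- function(stream, trigger_g = 0.01, stim_s = 5,
                                      freq_hz = 40, duty = 0.2,
                                      amplitude_v = 5) {
  stopifnot(inherits(stream, "intake_stream"))
  stop_if_not_scalar_pos(trigger_g, "trigger_g")
  v <- stream$cumulative_g
  if (any(diff(v) < 0)) {
    stop("stream must be cleaned (monotone) before scheduling", call. = FALSE)
  }
  inc <- diff(c(v[1L], v))
  # quanta completed by each tick, robust to 0.01-g float representation
  units <- diff(c(0, floor((cumsum(inc) + 1e-9) / trigger_g)))
  trig_ticks <- which(units > 0)
  n_triggers <- sum(units)
  if (n_triggers == 0L) {
    intervals <- data.frame(on_start = numeric(0), on_end = numeric(0))
  } else {
    t0 <- stream$timestamps[trig_ticks]
    t1 <- t0 + stim_s
    # merge overlapping bouts
    on_start <- t0[1L]; on_end <- t1[1L]
    starts <- c(); ends <- c()
    if (length(t0) > 1L) {
      for (i in 2L:length(t0)) {
        if (t0[i] <= on_end) {
          on_end <- max(on_end, t1[i])
        } else {
          starts <- c(starts, on_start); ends <- c(ends, on_end)
          on_start <- t0[i]; on_end <- t1[i]
        }
      }
    }
    starts <- c(starts, on_start); ends <- c(ends, on_end)
    intervals <- data.frame(on_start = starts, on_end = ends)
  }
  structure(
    list(intervals = intervals, pulse_width_s = duty / freq_hz,
         total_on_s = sum(intervals$on_end - intervals$on_start),
         n_triggers = as.integer(n_triggers),
         freq_hz = freq_hz, duty = duty, amplitude_v = amplitude_v,
         trigger = "intake"),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %s: %d on-interval(s), %.1f min on, pulse %.1f ms @ %g Hz (%g V)\n",
    x$trigger, nrow(x$intervals), x$total_on_s / 60,
    1000 * x$pulse_width_s, x$freq_hz, x$amplitude_v))
  invisible(x)
}
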