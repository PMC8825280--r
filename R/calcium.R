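# Calcium-imaging response classification: ratiometric (Fluo-4/Fura Red)
# in vitro traces, single-channel dF/F in vivo traces, and responder-overlap
# summaries.

#' Construct a ratiometric calcium trace
#'
#' Two-channel (Fluo-4 / Fura Red) fluorescence time series for one cell,
#' with the stimulus windows applied during the recording and the terminal
#' high-potassium (KCl) viability window.
#'
#' @param times Frame times in seconds (default frame interval 1.5 s).
#' @param fluo4,furared Fluorescence of each channel (arbitrary units, same
#'   length as `times`; Fura Red must be strictly positive).
#' @param cell_id Cell identifier.
#' @param stimulus_windows Data frame with columns `name`, `onset`,
#'   `duration` (seconds).
#' @param kcl_window Length-2 numeric `c(onset, duration)` of the KCl window.
#' @return An object of class `ratiometric_trace`.
#' @export
ratiometric_trace <- function(times, fluo4, furared, cell_id,
                              stimulus_windows, kcl_window) {
  stopifnot(length(times) == length(fluo4),
            length(times) == length(furared))
  if (any(furared <= 0)) {
    stop(sprintf("Fura Red must be positive at every frame (first bad frame: %d)",
                 which(furared <= 0)[1L]), call. = FALSE)
  }
  stopifnot(is.data.frame(stimulus_windows),
            all(c("name", "onset", "duration") %in% names(stimulus_windows)),
            length(kcl_window) == 2L)
  structure(
    list(times = as.numeric(times), fluo4 = as.numeric(fluo4),
         furared = as.numeric(furared), cell_id = cell_id,
         stimulus_windows = stimulus_windows,
         kcl_window = as.numeric(kcl_window)),
    class = "ratiometric_trace"
  )
}

#' Fluorescence ratio R = Fluo-4 / Fura Red
#'
#' @param trace A [ratiometric_trace()].
#' @return Numeric vector of the per-frame ratio.
#' @export
compute_ratio <- function(trace) {
  stopifnot(inherits(trace, "ratiometric_trace"))
  bad <- which(trace$furared <= 0)
  if (length(bad)) {
    stop(sprintf("Fura Red is non-positive at frame %d", bad[1L]),
         call. = FALSE)
  }
  trace$fluo4 / trace$furared
}

#' Call a per-stimulus calcium response on a ratio series
#'
#' The baseline is the mean of the `baseline_frames` frames immediately
#' preceding the window onset (the rebaseline rule; with
#' `rebaseline = FALSE` a caller-supplied `initial_baseline` is used
#' instead). A positive response is a fractional increase of the ratio above
#' baseline strictly greater than `threshold_frac` anywhere in the window.
#'
#' @param ratio Numeric ratio (or dF/F reference) series.
#' @param times Frame times matching `ratio`.
#' @param window Length-2 numeric `c(onset, duration)` in seconds.
#' @param baseline_frames Number of pre-window frames averaged for the
#'   baseline (default 5).
#' @param threshold_frac Call threshold as a fraction (default 0.10, i.e.
#'   a >10% increase; the comparison is strict).
#' @param rebaseline Use the frames immediately before this window
#'   (default `TRUE`); otherwise use `initial_baseline`.
#' @param initial_baseline Baseline ratio used when `rebaseline = FALSE`.
#' @return List with `$responded`, `$peak_fractional_increase`,
#'   `$peak_value` and `$baseline_used`.
#' @export
call_response <- function(ratio, times, window, baseline_frames = 5,
                          threshold_frac = 0.10, rebaseline = TRUE,
                          initial_baseline = NULL) {
  stopifnot(length(ratio) == length(times), length(window) == 2L)
  onset <- window[1L]; dur <- window[2L]
  pre <- which(times < onset)
  in_win <- which(times >= onset & times <= onset + dur)
  if (!length(in_win)) stop("stimulus window lies outside the trace", call. = FALSE)
  if (rebaseline) {
    if (length(pre) < baseline_frames) {
      stop(sprintf("need %d frames before the window, found %d",
                   baseline_frames, length(pre)), call. = FALSE)
    }
    baseline <- mean(ratio[utils::tail(pre, baseline_frames)])
  } else {
    if (is.null(initial_baseline)) {
      stop("initial_baseline required when rebaseline = FALSE", call. = FALSE)
    }
    baseline <- initial_baseline
  }
  if (baseline <= 0) stop("baseline ratio must be positive", call. = FALSE)
  peak <- max(ratio[in_win])
  frac <- (peak - baseline) / baseline
  list(responded = frac > threshold_frac,
       peak_fractional_increase = frac,
       peak_value = peak,
       baseline_used = baseline)
}

#' KCl viability gate
#'
#' A cell is viable if its ratio increases by more than `threshold_frac`
#' above baseline during the terminal KCl window; cells failing the gate are
#' excluded from all response analyses.
#'
#' @inheritParams call_response
#' @param kcl_window Length-2 numeric `c(onset, duration)`.
#' @return List with `$viable`, `$kcl_peak` (fractional increase) and
#'   `$baseline_used`.
#' @export
viability_gate <- function(ratio, times, kcl_window, baseline_frames = 5,
                           threshold_frac = 0.10) {
  res <- call_response(ratio, times, kcl_window,
                       baseline_frames = baseline_frames,
                       threshold_frac = threshold_frac)
  list(viable = res$responded,
       kcl_peak = res$peak_fractional_increase,
       baseline_used = res$baseline_used)
}

#' Normalize stimulus peaks to the peak KCl response
#'
#' @param peaks Numeric vector of per-stimulus peak values.
#' @param kcl_peak Peak KCl response (> 0).
#' @return `peaks / kcl_peak`.
#' @export
normalize_to_kcl <- function(peaks, kcl_peak) {
  stop_if_not_scalar_pos(kcl_peak, "kcl_peak")
  peaks / kcl_peak
}

#' Classify a population of ratiometric traces
#'
#' Runs ratio computation, the KCl viability gate and per-stimulus response
#' calls for every cell. Non-viable cells carry no stimulus calls.
#'
#' @param traces List of [ratiometric_trace()] objects.
#' @param threshold_frac Response-call threshold (default 0.10).
#' @param baseline_frames Pre-window frames averaged for baselines.
#' @return An object of class `response_calls`: `$calls` (one row per viable
#'   cell per stimulus: `unit_id`, `stimulus`, `responded`, `peak_frac`,
#'   `peak_norm_kcl`, `baseline`) and `$viability` (one row per cell:
#'   `unit_id`, `viable`, `kcl_peak`).
#' @export
classify_population <- function(traces, threshold_frac = 0.10,
                                baseline_frames = 5) {
  stopifnot(is.list(traces))
  viab <- list(); calls <- list()
  for (tr in traces) {
    stopifnot(inherits(tr, "ratiometric_trace"))
    r <- compute_ratio(tr)
    gate <- viability_gate(r, tr$times, tr$kcl_window,
                           baseline_frames = baseline_frames,
                           threshold_frac = threshold_frac)
    viab[[length(viab) + 1L]] <- data.frame(
      unit_id = tr$cell_id, viable = gate$viable, kcl_peak = gate$kcl_peak,
      stringsAsFactors = FALSE)
    if (!gate$viable) next
    for (i in seq_len(nrow(tr$stimulus_windows))) {
      w <- tr$stimulus_windows[i, ]
      res <- call_response(r, tr$times, c(w$onset, w$duration),
                           baseline_frames = baseline_frames,
                           threshold_frac = threshold_frac)
      calls[[length(calls) + 1L]] <- data.frame(
        unit_id = tr$cell_id, stimulus = w$name, responded = res$responded,
        peak_frac = res$peak_fractional_increase,
        peak_norm_kcl = normalize_to_kcl(res$peak_fractional_increase,
                                         gate$kcl_peak),
        baseline = res$baseline_used, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(calls = if (length(calls)) do.call(rbind, calls) else
           data.frame(unit_id = character(), stimulus = character(),
                      responded = logical(), peak_frac = numeric(),
                      peak_norm_kcl = numeric(), baseline = numeric()),
         viability = if (length(viab)) do.call(rbind, viab) else
           data.frame(unit_id = character(), viable = logical(),
                      kcl_peak = numeric())),
    class = "response_calls"
  )
}

#' Build response calls from externally supplied booleans
#'
#' For assays whose per-unit responses are recorded outside this package
#' (for example excitatory currents in coculture patch clamp), this wraps
#' two logical vectors into the same `response_calls` structure consumed by
#' [venn_summary()]. All units are treated as viable.
#'
#' @param responded_a,responded_b Logical vectors (same length), one entry
#'   per unit.
#' @param stim_a,stim_b Stimulus names.
#' @param unit_id Optional unit identifiers.
#' @return A `response_calls` object.
#' @export
response_calls_from_logical <- function(responded_a, responded_b,
                                        stim_a = "a", stim_b = "b",
                                        unit_id = NULL) {
  stopifnot(length(responded_a) == length(responded_b))
  n <- length(responded_a)
  if (is.null(unit_id)) unit_id <- sprintf("unit_%03d", seq_len(n))
  calls <- rbind(
    data.frame(unit_id = unit_id, stimulus = stim_a,
               responded = as.logical(responded_a), peak_frac = NA_real_,
               peak_norm_kcl = NA_real_, baseline = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(unit_id = unit_id, stimulus = stim_b,
               responded = as.logical(responded_b), peak_frac = NA_real_,
               peak_norm_kcl = NA_real_, baseline = NA_real_,
               stringsAsFactors = FALSE))
  structure(
    list(calls = calls,
         viability = data.frame(unit_id = unit_id, viable = TRUE,
                                kcl_peak = NA_real_,
                                stringsAsFactors = FALSE)),
    class = "response_calls"
  )
}

#' Responder-overlap (Venn) summary for two stimuli
#'
#' Partitions viable units into a-only / b-only / both / neither and reports
#' class percentages both among responders (units responding to at least one
#' stimulus) and among all viable units.
#'
#' @param calls A `response_calls` object ([classify_population()] or
#'   [response_calls_from_logical()]).
#' @param stim_a,stim_b Stimulus names present in `calls$calls$stimulus`.
#' @return An object of class `venn_summary` with `$n_viable`,
#'   `$n_responders`, `$counts` (named: `a_only`, `b_only`, `both`,
#'   `neither`), `$pct_of_responders` and `$pct_of_viable`.
#' @export
venn_summary <- function(calls, stim_a, stim_b) {
  stopifnot(inherits(calls, "response_calls"))
  viable_ids <- calls$viability$unit_id[calls$viability$viable]
  if (!length(viable_ids)) stop("no viable units", call. = FALSE)
  df <- calls$calls
  df <- df[df$unit_id %in% viable_ids, , drop = FALSE]
  resp_for <- function(stim) {
    sub <- df[df$stimulus == stim, ]
    stats::setNames(sub$responded, sub$unit_id)[as.character(viable_ids)]
  }
  a <- resp_for(stim_a); b <- resp_for(stim_b)
  if (anyNA(a) || anyNA(b)) {
    stop(sprintf("missing calls for stimulus '%s' or '%s' on some viable units",
                 stim_a, stim_b), call. = FALSE)
  }
  counts <- c(a_only = sum(a & !b), b_only = sum(!a & b),
              both = sum(a & b), neither = sum(!a & !b))
  n_resp <- sum(counts[c("a_only", "b_only", "both")])
  pct_resp <- if (n_resp > 0) {
    100 * counts[c("a_only", "b_only", "both")] / n_resp
  } else {
    stats::setNames(rep(NA_real_, 3L), c("a_only", "b_only", "both"))
  }
  structure(
    list(stim_a = stim_a, stim_b = stim_b,
         n_viable = length(viable_ids), n_responders = n_resp,
         counts = counts,
         pct_of_responders = pct_resp,
         pct_of_viable = 100 * counts / length(viable_ids)),
    class = "venn_summary"
  )
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> %s vs %s: %d viable, %d responders\n",
              x$stim_a, x$stim_b, x$n_viable, x$n_responders))
  cat(sprintf("  counts: %s-only %d, %s-only %d, both %d, neither %d\n",
              x$stim_a, x$counts[["a_only"]], x$stim_b, x$counts[["b_only"]],
              x$counts[["both"]], x$counts[["neither"]]))
  if (x$n_responders > 0) {
    cat(sprintf("  %% of responders: %.1f / %.1f / %.1f\n",
                x$pct_of_responders[["a_only"]], x$pct_of_responders[["b_only"]],
                x$pct_of_responders[["both"]]))
  }
  cat(sprintf("  %% of viable: %.1f / %.1f / %.1f / %.1f\n",
              x$pct_of_viable[["a_only"]], x$pct_of_viable[["b_only"]],
              x$pct_of_viable[["both"]], x$pct_of_viable[["neither"]]))
  invisible(x)
}

#' Construct a single-channel fluorescence trace
#'
#' @param times Frame times in seconds.
#' @param f Fluorescence values (finite, positive mean).
#' @param neuron_id Unit identifier.
#' @param stimulus_windows Data frame with `name`, `onset`, `duration`.
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(times, f, neuron_id, stimulus_windows) {
  stopifnot(length(times) == length(f), all(is.finite(f)))
  if (mean(f) <= 0) stop("mean fluorescence must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), f = as.numeric(f),
                 neuron_id = neuron_id, stimulus_windows = stimulus_windows),
            class = "dff_trace")
}

#' Whole-run dF/F series
#'
#' `dF/F = (F - mean(F over the entire run)) / mean(F over the entire run)`;
#' the returned series therefore has mean exactly zero.
#'
#' @param trace A [dff_trace()].
#' @return Numeric dF/F series.
#' @export
compute_dff <- function(trace) {
  stopifnot(inherits(trace, "dff_trace"))
  m <- mean(trace$f)
  if (m <= 0) stop("mean fluorescence must be positive", call. = FALSE)
  (trace$f - m) / m
}

#' Call a dF/F response for one stimulus window
#'
#' Because the dF/F definition references the whole-run mean, the
#' per-stimulus baseline is the mean dF/F over `baseline_s` seconds
#' immediately preceding the window onset; a positive response is a maximum
#' in-window dF/F exceeding that level by more than `threshold_frac`
#' (default 0.20, i.e. a >20% increase).
#'
#' @param dff Numeric dF/F series.
#' @param times Frame times matching `dff`.
#' @param window Length-2 numeric `c(onset, duration)`.
#' @param threshold_frac Call threshold (default 0.20, strict).
#' @param baseline_s Pre-window seconds averaged for the baseline level
#'   (default 30).
#' @return List with `$responded`, `$peak_dff`, `$baseline_level` and
#'   `$peak_over_baseline`.
#' @export
call_dff_response <- function(dff, times, window, threshold_frac = 0.20,
                              baseline_s = 30) {
  stopifnot(length(dff) == length(times), length(window) == 2L)
  onset <- window[1L]; dur <- window[2L]
  pre <- which(times >= onset - baseline_s & times < onset)
  in_win <- which(times >= onset & times <= onset + dur)
  if (!length(pre)) stop("no pre-stimulus frames for the baseline", call. = FALSE)
  if (!length(in_win)) stop("stimulus window lies outside the trace", call. = FALSE)
  base <- mean(dff[pre])
  peak <- max(dff[in_win])
  list(responded = (peak - base) > threshold_frac,
       peak_dff = peak,
       baseline_level = base,
       peak_over_baseline = peak - base)
}

#' Classify a population of single-channel dF/F traces
#'
#' @param traces List of [dff_trace()] objects.
#' @param threshold_frac Call threshold (default 0.20).
#' @param baseline_s Pre-window baseline duration, seconds.
#' @return A `response_calls` object (all units treated as viable: the in
#'   vivo preparation has no terminal KCl gate).
#' @export
classify_dff_population <- function(traces, threshold_frac = 0.20,
                                    baseline_s = 30) {
  calls <- list(); ids <- character(0)
  for (tr in traces) {
    stopifnot(inherits(tr, "dff_trace"))
    dff <- compute_dff(tr)
    ids <- c(ids, tr$neuron_id)
    for (i in seq_len(nrow(tr$stimulus_windows))) {
      w <- tr$stimulus_windows[i, ]
      res <- call_dff_response(dff, tr$times, c(w$onset, w$duration),
                               threshold_frac = threshold_frac,
                               baseline_s = baseline_s)
      calls[[length(calls) + 1L]] <- data.frame(
        unit_id = tr$neuron_id, stimulus = w$name, responded = res$responded,
        peak_frac = res$peak_over_baseline, peak_norm_kcl = NA_real_,
        baseline = res$baseline_level, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(calls = do.call(rbind, calls),
         viability = data.frame(unit_id = ids, viable = TRUE,
                                kcl_peak = NA_real_, stringsAsFactors = FALSE)),
    class = "response_calls"
  )
}
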