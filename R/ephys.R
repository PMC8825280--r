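# Whole-nerve extracellular electrophysiology: spike detection, firing-rate
# estimation and baseline-normalized response metrics.

#' Construct a voltage trace
#'
#' Container for a raw extracellular recording. No spike sorting is attempted
#' anywhere in this module: whole-nerve recordings pool all units, so every
#' threshold crossing counts as multiunit activity.
#'
#' @param samples Numeric vector of voltage samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, sampling_rate, start_time = 0) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (length(samples) && !all(is.finite(samples))) {
    stop("voltage samples must all be finite", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         start_time = start_time),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.1f s from t = %g s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$start_time))
  invisible(x)
}

#' Detect multiunit spikes by an RMS-noise threshold
#'
#' The detection threshold is `k` times the root-mean-square of the trace
#' (computed over `rms_window_s` seconds from the start of the trace, or the
#' whole trace by default). A spike is the time of the absolute-amplitude
#' extremum of each supra-threshold excursion of `|v|`; excursions whose
#' extrema fall within `refractory_s` of the previous accepted spike are
#' merged into it (the merged event keeps the larger extremum's time).
#'
#' @param trace A [voltage_trace()].
#' @param k Threshold multiplier on the RMS noise estimate (> 0, default 4).
#' @param rms_window_s Length of the initial segment used to estimate RMS,
#'   in seconds, or `NULL` (default) for the whole trace.
#' @param refractory_s Minimum separation between detected events (seconds).
#' @return An object of class `spike_train` with strictly increasing
#'   `$spike_times` (seconds) and the detection parameters used.
#' @export
detect_spikes <- function(trace, k = 4, rms_window_s = NULL,
                          refractory_s = 0.001) {
  stopifnot(inherits(trace, "voltage_trace"))
  stop_if_not_scalar_pos(k, "k")
  v <- trace$samples
  if (!all(is.finite(v))) stop("trace contains non-finite samples", call. = FALSE)
  fs <- trace$sampling_rate
  n <- length(v)
  if (n == 0L) return(spike_train(numeric(0), k, rms_window_s, refractory_s))

  rms_n <- if (is.null(rms_window_s)) n else min(n, max(2L, round(rms_window_s * fs)))
  rms <- sqrt(mean(v[seq_len(rms_n)]^2))
  thr <- k * rms
  if (thr == 0) return(spike_train(numeric(0), k, rms_window_s, refractory_s))

  above <- abs(v) > thr
  if (!any(above)) return(spike_train(numeric(0), k, rms_window_s, refractory_s))

  # excursion boundaries from run-length encoding of the supra-threshold mask
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]

  ev_idx <- mapply(function(s, e) {
    seg <- abs(v[s:e])
    s + which.max(seg) - 1L
  }, starts, ends)
  ev_amp <- abs(v[ev_idx])
  ev_t <- trace$start_time + (ev_idx - 1L) / fs

  # merge events closer than the refractory period, keeping the larger one
  if (length(ev_t) > 1L) {
    keep_t <- numeric(length(ev_t)); keep_a <- numeric(length(ev_t))
    m <- 1L
    keep_t[1L] <- ev_t[1L]; keep_a[1L] <- ev_amp[1L]
    for (i in 2L:length(ev_t)) {
      if (ev_t[i] - keep_t[m] < refractory_s) {
        if (ev_amp[i] > keep_a[m]) { keep_t[m] <- ev_t[i]; keep_a[m] <- ev_amp[i] }
      } else {
        m <- m + 1L
        keep_t[m] <- ev_t[i]; keep_a[m] <- ev_amp[i]
      }
    }
    ev_t <- keep_t[seq_len(m)]
  }
  spike_train(ev_t, k, rms_window_s, refractory_s)
}

#' Construct a spike train
#'
#' @param spike_times Strictly increasing event times in seconds.
#' @param k,rms_window_s,refractory_s Detection parameters (recorded for
#'   provenance; `NULL` window means whole-trace RMS).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, k = NA_real_, rms_window_s = NULL,
                        refractory_s = NA_real_) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(spike_times = spike_times,
         detection_params = list(k = k, rms_window_s = rms_window_s,
                                 refractory_s = refractory_s)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$spike_times)))
  if (length(x$spike_times)) {
    cat(sprintf(" in [%.3f, %.3f] s", min(x$spike_times), max(x$spike_times)))
  }
  cat("\n")
  invisible(x)
}

#' Gaussian-kernel firing-rate estimate
#'
#' Evaluates `rate(t) = sum_i dnorm(t - t_i, sd = kernel_sigma_s)` at the
#' centers of contiguous bins of width `bin_width_s` covering
#' `[t_start, t_end]`. Each kernel integrates to one spike, so for spikes at
#' least ~3 sigma away from the window edges the summed `rate * bin_width`
#' mass equals the spike count. No edge padding is applied.
#'
#' @param train A [spike_train()].
#' @param t_start,t_end Window covered by the series, seconds (`t_end >
#'   t_start`).
#' @param bin_width_s Bin width in seconds (default 0.2, i.e. 200-ms bins).
#' @param kernel_sigma_s Gaussian kernel standard deviation in seconds
#'   (default equal to the bin width).
#' @return An object of class `firing_rate_series` with `$bin_centers` (s),
#'   `$rate` (Hz), `$bin_width` and `$kernel_sigma`.
#' @export
estimate_firing_rate <- function(train, t_start, t_end, bin_width_s = 0.2,
                                 kernel_sigma_s = bin_width_s) {
  stopifnot(inherits(train, "spike_train"))
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  stop_if_not_scalar_pos(bin_width_s, "bin_width_s")
  stop_if_not_scalar_pos(kernel_sigma_s, "kernel_sigma_s")

  centers <- seq(t_start + bin_width_s / 2, t_end, by = bin_width_s)
  rate <- numeric(length(centers))
  half <- 8 * kernel_sigma_s  # truncation; tail mass < 1e-15
  for (ti in train$spike_times) {
    lo <- max(1L, ceiling((ti - half - centers[1L]) / bin_width_s) + 1L)
    hi <- min(length(centers), floor((ti + half - centers[1L]) / bin_width_s) + 1L)
    if (lo <= hi) {
      idx <- lo:hi
      rate[idx] <- rate[idx] + stats::dnorm(centers[idx], mean = ti,
                                            sd = kernel_sigma_s)
    }
  }
  structure(
    list(bin_centers = centers, rate = rate, bin_width = bin_width_s,
         kernel_sigma = kernel_sigma_s),
    class = "firing_rate_series"
  )
}

#' @export
print.firing_rate_series <- function(x, ...) {
  cat(sprintf(
    "<firing_rate_series> %d bins of %g s (sigma %g s), mean rate %.2f Hz\n",
    length(x$rate), x$bin_width, x$kernel_sigma, mean(x$rate)))
  invisible(x)
}

#' Normalize a firing-rate series to its pre-stimulus baseline
#'
#' Each trial serves as its own control: the rate is divided by the mean
#' rate over the baseline window (by default the first 120 s, i.e. the 2-min
#' pre-stimulus period). A subtractive mode is available behind
#' `mode = "subtract"` for recordings where a ratio is not meaningful.
#'
#' @param series A [estimate_firing_rate()] result covering the baseline
#'   window.
#' @param baseline_start Start of the baseline window, seconds.
#' @param baseline_dur_s Baseline duration in seconds (default 120).
#' @param mode `"ratio"` (default, fold-of-baseline) or `"subtract"`.
#' @return A list with `$series` (the normalized `firing_rate_series`) and
#'   `$baseline_rate` in Hz.
#' @export
normalize_to_baseline <- function(series, baseline_start = 0,
                                  baseline_dur_s = 120,
                                  mode = c("ratio", "subtract")) {
  stopifnot(inherits(series, "firing_rate_series"))
  mode <- match.arg(mode)
  in_base <- series$bin_centers >= baseline_start &
    series$bin_centers < baseline_start + baseline_dur_s
  if (!any(in_base)) {
    stop("series does not cover the baseline window", call. = FALSE)
  }
  baseline <- mean(series$rate[in_base])
  out <- series
  if (mode == "ratio") {
    if (baseline == 0) {
      stop(paste("baseline mean rate is zero; fold-of-baseline normalization",
                 "is undefined - analyze raw rates or use mode = \"subtract\""),
           call. = FALSE)
    }
    out$rate <- series$rate / baseline
  } else {
    out$rate <- series$rate - baseline
  }
  list(series = out, baseline_rate = baseline)
}

#' Define a stimulus infusion event
#'
#' @param stimulus Stimulus name.
#' @param onset Infusion onset, seconds.
#' @param duration Infusion duration, seconds (default 60; a 1-min
#'   perfusion).
#' @param window_end End of the analysis window, seconds (default `onset +
#'   360`: infusions are separated by at least 6 min).
#' @return An object of class `infusion_event`.
#' @export
infusion_event <- function(stimulus, onset, duration = 60,
                           window_end = onset + 360) {
  stopifnot(onset >= 0, duration > 0)
  if (window_end <= onset) stop("window_end must exceed onset", call. = FALSE)
  structure(list(stimulus = stimulus, onset = onset, duration = duration,
                 window_end = window_end),
            class = "infusion_event")
}

#' Quantify a stimulation response on a normalized firing-rate series
#'
#' Peak response is the maximum of the (baseline-normalized) rate within
#' `[onset, window_end]`; time to peak is measured from infusion onset to
#' that maximum; the area under the curve is the signed trapezoidal integral
#' of `(rate - 1)` over the window (set `positive_part = TRUE` to floor
#' negative excursions at zero).
#'
#' @param series A baseline-normalized `firing_rate_series` (see
#'   [normalize_to_baseline()]).
#' @param event An [infusion_event()] whose window lies inside the series.
#' @param positive_part If `TRUE`, integrate only positive deviations from
#'   baseline. Default `FALSE` (signed AUC).
#' @return A list of class `response_metrics`: `$peak_norm`, `$time_to_peak`
#'   (s), `$auc`, `$baseline_level` (the reference level subtracted in the
#'   AUC, 1 for ratio-normalized series) and `$raw_peak_rate`.
#' @export
quantify_response <- function(series, event, positive_part = FALSE) {
  stopifnot(inherits(series, "firing_rate_series"),
            inherits(event, "infusion_event"))
  in_win <- series$bin_centers >= event$onset &
    series$bin_centers <= event$window_end
  if (!any(in_win)) stop("event window lies outside the series", call. = FALSE)
  t_w <- series$bin_centers[in_win]
  r_w <- series$rate[in_win]
  i_max <- which.max(r_w)
  dev <- r_w - 1
  if (positive_part) dev <- pmax(dev, 0)
  structure(
    list(peak_norm = r_w[i_max],
         time_to_peak = t_w[i_max] - event$onset,
         auc = trapz(t_w, dev),
         baseline_level = 1,
         raw_peak_rate = r_w[i_max]),
    class = "response_metrics"
  )
}

#' @export
print.response_metrics <- function(x, ...) {
  cat(sprintf(
    "<response_metrics> peak %.3f x baseline @ %.2f s after onset, AUC %.3f\n",
    x$peak_norm, x$time_to_peak, x$auc))
  invisible(x)
}
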