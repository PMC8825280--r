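# Seeded synthetic-data generators. Each generator returns its simulated
# input together with a `ground_truth` object carrying the design labels
# (exact spike times, responder classes, DE flags, true preference, true
# attenuation), so every downstream stage can be validated against a known
# answer. Identical (parameters, seed) always reproduce identical output,
# and generators restore the caller's RNG state.

#' Ground-truth sidecar for a generated data set
#'
#' @param kind Generator name.
#' @param params Named list of the generator parameters used.
#' @param labels Named list of per-unit truth (spike times, classes, flags).
#' @param seed Integer seed that produced the data.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kind, params, labels, seed) {
  structure(list(kind = kind, params = params, labels = labels, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %d): labels %s\n", x$kind,
              x$seed, paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

#' Simulate a whole-nerve vagal recording
#'
#' Spike times are drawn from an inhomogeneous Poisson process whose rate is
#' `baseline_rate_hz` multiplied by each response epoch's rate multiplier
#' inside its window (piecewise constant). The voltage trace is Gaussian
#' noise plus a stereotyped biphasic 1-ms spike template scaled to
#' `spike_amplitude_uv` at every spike time.
#'
#' @param duration_s Recording length in seconds (intended use records at
#'   least 2 min of baseline before stimulation, so >= 240 s for default
#'   analyses).
#' @param sampling_rate_hz Sampling rate (default 10000).
#' @param baseline_rate_hz Baseline multiunit firing rate (>= 0).
#' @param response_profile List of `c(onset_s, duration_s, rate_multiplier)`
#'   response epochs (multipliers >= 0, windows inside the recording).
#' @param spike_amplitude_uv Template peak amplitude (default 80 uV).
#' @param noise_sd_uv Additive Gaussian noise s.d. (default 8 uV).
#' @param seed Integer seed.
#' @return List with `$trace` ([voltage_trace()]) and `$truth`
#'   ([ground_truth()] with `labels$spike_times`).
#' @export
gen_vagal_recording <- function(duration_s, sampling_rate_hz = 10000,
                                baseline_rate_hz = 10,
                                response_profile = list(),
                                spike_amplitude_uv = 80, noise_sd_uv = 8,
                                seed = 1) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  stopifnot(baseline_rate_hz >= 0, noise_sd_uv >= 0)
  profile <- lapply(response_profile, function(w) {
    w <- as.numeric(w)
    if (length(w) != 3L) stop("response epochs are c(onset, duration, multiplier)",
                              call. = FALSE)
    if (w[3L] < 0) stop("rate multipliers must be >= 0", call. = FALSE)
    if (w[1L] < 0 || w[1L] + w[2L] > duration_s) {
      stop("response window outside the recording", call. = FALSE)
    }
    w
  })

  # piecewise-constant rate over segments bounded by window edges
  edges <- sort(unique(c(0, duration_s,
                         unlist(lapply(profile, function(w) c(w[1L], w[1L] + w[2L]))))))
  rate_at <- function(t) {
    r <- baseline_rate_hz
    for (w in profile) if (t >= w[1L] && t < w[1L] + w[2L]) r <- r * w[3L]
    r
  }

  local_seed(seed, {
    spikes <- numeric(0)
    for (i in seq_len(length(edges) - 1L)) {
      a <- edges[i]; b <- edges[i + 1L]
      lambda <- rate_at(a) * (b - a)
      n <- stats::rpois(1L, lambda)
      if (n > 0L) spikes <- c(spikes, sort(stats::runif(n, a, b)))
    }
    spikes <- sort(spikes)

    n_samp <- round(duration_s * sampling_rate_hz)
    v <- stats::rnorm(n_samp, sd = noise_sd_uv)
    # biphasic 1-ms template: positive then negative lobe, unit peak
    n_t <- max(2L, round(0.001 * sampling_rate_hz))
    template <- sin(2 * pi * seq(0, 1, length.out = n_t)) * spike_amplitude_uv
    for (ts in spikes) {
      i0 <- floor(ts * sampling_rate_hz) + 1L
      idx <- i0:min(n_samp, i0 + n_t - 1L)
      v[idx] <- v[idx] + template[seq_along(idx)]
    }
    list(
      trace = voltage_trace(v, sampling_rate_hz),
      truth = ground_truth(
        "vagal_recording",
        params = list(duration_s = duration_s,
                      sampling_rate_hz = sampling_rate_hz,
                      baseline_rate_hz = baseline_rate_hz,
                      response_profile = profile,
                      spike_amplitude_uv = spike_amplitude_uv,
                      noise_sd_uv = noise_sd_uv),
        labels = list(spike_times = spikes), seed = seed)
    )
  })
}

#' Simulate a population of ratiometric calcium-imaging traces
#'
#' Each 210-s trace carries two 15-s stimulus windows (buffer perfused in
#' between) and a terminal KCl viability window. Designed responders receive
#' a half-sine ratio transient peaking at `responder_peak_frac` above
#' baseline in their assigned windows; non-assigned windows and non-viable
#' cells peak at `nonresponder_peak_frac`. Construction margins are
#' enforced: any designed peak within one percentage point of the 10% call
#' threshold is rejected, so downstream classification of the fixture is
#' unambiguous.
#'
#' @param n_neither,n_a_only,n_b_only,n_both Viable cell counts per
#'   responder class (`neither` responds only to KCl).
#' @param n_nonviable Cells designed to fail the KCl gate.
#' @param frame_interval_s Frame interval (default 1.5 s).
#' @param responder_peak_frac Designed responder peak as a fraction above
#'   baseline (default 0.25; must exceed 0.10 by the margin).
#' @param nonresponder_peak_frac Sub-threshold peak for unassigned stimuli
#'   (default 0.05; must stay below 0.10 by the margin).
#' @param kcl_peak_frac KCl peak for viable cells (default 0.15).
#' @param noise_sd Frame-to-frame ratio noise s.d. (default 0.004).
#' @param stim_names Names of the two experimental stimuli.
#' @param seed Integer seed.
#' @return List with `$traces` (list of [ratiometric_trace()]) and `$truth`
#'   (`labels$class`: data frame `cell_id`, `class`).
#' @export
gen_calcium_population <- function(n_neither, n_a_only, n_b_only, n_both,
                                   n_nonviable = 0, frame_interval_s = 1.5,
                                   responder_peak_frac = 0.25,
                                   nonresponder_peak_frac = 0.05,
                                   kcl_peak_frac = 0.15, noise_sd = 0.004,
                                   stim_names = c("glucose", "sucralose"),
                                   seed = 1) {
  counts <- c(n_neither, n_a_only, n_b_only, n_both, n_nonviable)
  stopifnot(all(counts >= 0), length(stim_names) == 2L)
  threshold <- 0.10; margin <- 0.01
  for (frac in c(responder_peak_frac, nonresponder_peak_frac, kcl_peak_frac)) {
    if (abs(frac - threshold) < margin) {
      stop(sprintf(paste("designed peak fraction %.3f is within 1%% of the",
                         "10%% call threshold; fixture would be ambiguous"),
                   frac), call. = FALSE)
    }
  }
  if (responder_peak_frac <= threshold || nonresponder_peak_frac >= threshold) {
    stop("need responder_peak_frac > 0.10 > nonresponder_peak_frac",
         call. = FALSE)
  }
  if (sum(counts[1:4]) > 0 && kcl_peak_frac <= threshold) {
    stop("viable cells require kcl_peak_frac > 0.10", call. = FALSE)
  }

  total_s <- 210
  times <- seq(0, total_s - frame_interval_s, by = frame_interval_s)
  windows <- data.frame(name = stim_names, onset = c(45, 90),
                        duration = c(15, 15), stringsAsFactors = FALSE)
  kcl <- c(150, 30)
  classes <- rep(c("neither", "a_only", "b_only", "both", "nonviable"), counts)

  bump <- function(onset, dur, amp) {
    ifelse(times >= onset & times <= onset + dur,
           amp * sin(pi * pmin(pmax((times - onset) / dur, 0), 1)), 0)
  }

  local_seed(seed, {
    classes <- sample(classes)  # shuffle so class is not encoded in cell order
    traces <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cls <- classes[i]
      amp_a <- if (cls %in% c("a_only", "both")) responder_peak_frac else
        nonresponder_peak_frac
      amp_b <- if (cls %in% c("b_only", "both")) responder_peak_frac else
        nonresponder_peak_frac
      amp_k <- if (cls == "nonviable") nonresponder_peak_frac else kcl_peak_frac
      profile <- 1 + bump(windows$onset[1L], windows$duration[1L], amp_a) +
        bump(windows$onset[2L], windows$duration[2L], amp_b) +
        bump(kcl[1L], kcl[2L], amp_k) +
        stats::rnorm(length(times), sd = noise_sd)
      furared <- 100 + stats::rnorm(length(times), sd = 0.5)
      traces[[i]] <- ratiometric_trace(
        times = times, fluo4 = profile * furared, furared = furared,
        cell_id = sprintf("cell_%03d", i),
        stimulus_windows = windows, kcl_window = kcl)
    }
    list(
      traces = traces,
      truth = ground_truth(
        "calcium_population",
        params = list(counts = stats::setNames(counts,
                        c("neither", "a_only", "b_only", "both", "nonviable")),
                      frame_interval_s = frame_interval_s,
                      responder_peak_frac = responder_peak_frac,
                      nonresponder_peak_frac = nonresponder_peak_frac,
                      kcl_peak_frac = kcl_peak_frac, noise_sd = noise_sd,
                      stim_names = stim_names),
        labels = list(class = data.frame(
          cell_id = sprintf("cell_%03d", seq_along(classes)),
          class = classes, stringsAsFactors = FALSE)),
        seed = seed)
    )
  })
}

#' Simulate a population of in vivo single-channel dF/F traces
#'
#' Emulates two-photon imaging of vagal sensory neurons during back-to-back
#' intraduodenal infusions: each 480-s run has 2 min of baseline, a 60-s
#' window per stimulus and 2 min between and after. Designed responders
#' carry a half-sine fluorescence transient of fractional amplitude
#' `responder_peak` (well above the 20% call threshold); all other windows
#' stay at `nonresponder_peak`.
#'
#' @param n_neither,n_a_only,n_b_only,n_both Neuron counts per class.
#' @param frame_interval_s Frame interval (default 0.683 s).
#' @param responder_peak,nonresponder_peak Designed fractional transient
#'   amplitudes (defaults 0.5 and 0.05; each must be at least 0.02 away
#'   from the 0.20 threshold).
#' @param noise_sd Fractional fluorescence noise s.d. (default 0.01).
#' @param stim_names Names of the two stimuli.
#' @param seed Integer seed.
#' @return List with `$traces` (list of [dff_trace()]) and `$truth`.
#' @export
gen_dff_population <- function(n_neither, n_a_only, n_b_only, n_both = 0,
                               frame_interval_s = 0.683,
                               responder_peak = 0.5, nonresponder_peak = 0.05,
                               noise_sd = 0.01,
                               stim_names = c("sucrose", "sucralose"),
                               seed = 1) {
  counts <- c(n_neither, n_a_only, n_b_only, n_both)
  stopifnot(all(counts >= 0), length(stim_names) == 2L)
  threshold <- 0.20; margin <- 0.02
  for (p in c(responder_peak, nonresponder_peak)) {
    if (abs(p - threshold) < margin) {
      stop("designed peak within 2% of the 20% call threshold", call. = FALSE)
    }
  }
  if (responder_peak <= threshold || nonresponder_peak >= threshold) {
    stop("need responder_peak > 0.20 > nonresponder_peak", call. = FALSE)
  }
  total_s <- 480; f0 <- 100
  times <- seq(0, total_s - frame_interval_s, by = frame_interval_s)
  windows <- data.frame(name = stim_names, onset = c(120, 300),
                        duration = c(60, 60), stringsAsFactors = FALSE)
  classes <- rep(c("neither", "a_only", "b_only", "both"), counts)
  bump <- function(onset, dur, amp) {
    ifelse(times >= onset & times <= onset + dur,
           amp * sin(pi * pmin(pmax((times - onset) / dur, 0), 1)), 0)
  }
  local_seed(seed, {
    classes <- sample(classes)
    traces <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cls <- classes[i]
      amp_a <- if (cls %in% c("a_only", "both")) responder_peak else
        nonresponder_peak
      amp_b <- if (cls %in% c("b_only", "both")) responder_peak else
        nonresponder_peak
      f <- f0 * (1 + bump(windows$onset[1L], windows$duration[1L], amp_a) +
                   bump(windows$onset[2L], windows$duration[2L], amp_b) +
                   stats::rnorm(length(times), sd = noise_sd))
      traces[[i]] <- dff_trace(times, f, sprintf("neuron_%03d", i), windows)
    }
    list(
      traces = traces,
      truth = ground_truth(
        "dff_population",
        params = list(counts = stats::setNames(counts,
                        c("neither", "a_only", "b_only", "both")),
                      frame_interval_s = frame_interval_s,
                      responder_peak = responder_peak,
                      nonresponder_peak = nonresponder_peak,
                      noise_sd = noise_sd, stim_names = stim_names),
        labels = list(class = data.frame(
          neuron_id = sprintf("neuron_%03d", seq_along(classes)),
          class = classes, stringsAsFactors = FALSE)),
        seed = seed)
    )
  })
}

# inverse-CDF draw from a Normal truncated above at `upper`
rtnorm_below <- function(n, mean, sd, upper) {
  if (sd == 0) return(rep(min(mean, upper), n))
  p_up <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n) * p_up, mean, sd)
}

#' Simulate a Biomark-style single-cell Cq matrix
#'
#' Two cell groups (e.g. reporter-positive vs reporter-negative) with
#' optional planted log2 expression effects. Detected Cq values follow a
#' Normal distribution (mean `cq_mean` minus the gene's group-1 effect in
#' cycles, which equals the effect in log2 expression units) truncated below
#' the detection cutoff; a `dropout_prob` fraction of non-housekeeping wells
#' is undetected. Housekeeping genes are always detected except in designed
#' QC-casualty cells, which lack both and are therefore removed by
#' [quality_filter()].
#'
#' @param n_cells_per_group Integer vector of length 2 (default `c(60,
#'   30)`).
#' @param genes Character panel; housekeeping genes are appended if absent.
#' @param de_genes Named numeric vector of log2 effect sizes (positive =
#'   higher expression in group 1). Names must be panel genes.
#' @param dropout_prob Per-well dropout probability in `[0, 1)`.
#' @param cq_mean,cq_sd Mean and s.d. of detected Cq values (defaults 26
#'   and 0.8 cycles; `cq_mean` must be below the cutoff).
#' @param cq_cutoff Detection cutoff (default 34).
#' @param housekeeping Housekeeping genes (default `Gapdh`, `Actb1`).
#' @param group_labels Labels for the two groups.
#' @param n_mice Mice the cells are attributed to, round-robin (default 3).
#' @param n_qc_casualties Cells (taken from group 1) designed to lack both
#'   housekeeping genes.
#' @param n_low_quality_wells Wells given a quality score below 0.65.
#' @param seed Integer seed.
#' @return List with `$matrix` ([cq_matrix()]) and `$truth`
#'   (`labels$de_genes`, `labels$qc_casualties`).
#' @export
gen_cq_matrix <- function(n_cells_per_group = c(60, 30), genes,
                          de_genes = numeric(0), dropout_prob = 0,
                          cq_mean = 26, cq_sd = 0.8, cq_cutoff = 34,
                          housekeeping = c("Gapdh", "Actb1"),
                          group_labels = c("GFP+", "GFP-"), n_mice = 3,
                          n_qc_casualties = 0, n_low_quality_wells = 0,
                          seed = 1) {
  stopifnot(length(n_cells_per_group) == 2L, all(n_cells_per_group >= 0))
  if (cq_mean >= cq_cutoff) stop("cq_mean must be below cq_cutoff", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  genes <- union(genes, housekeeping)
  if (length(de_genes) && !all(names(de_genes) %in% genes)) {
    stop("effect listed for a gene not in the panel: ",
         paste(setdiff(names(de_genes), genes), collapse = ", "),
         call. = FALSE)
  }
  n1 <- n_cells_per_group[1L]; n2 <- n_cells_per_group[2L]
  n <- n1 + n2
  if (n_qc_casualties > n1) stop("more QC casualties than group-1 cells",
                                 call. = FALSE)
  group <- rep(group_labels, c(n1, n2))
  cell_id <- sprintf("cell_%03d", seq_len(n))
  mouse_id <- sprintf("mouse_%d", (seq_len(n) - 1L) %% n_mice + 1L)

  local_seed(seed, {
    cq <- matrix(NA_real_, n, length(genes),
                 dimnames = list(cell_id, genes))
    quality <- matrix(stats::runif(n * length(genes), 0.7, 1), n,
                      length(genes), dimnames = list(cell_id, genes))
    casualties <- if (n_qc_casualties > 0) {
      sample(cell_id[group == group_labels[1L]], n_qc_casualties)
    } else character(0)
    for (g in genes) {
      eff <- if (g %in% names(de_genes)) de_genes[[g]] else 0
      mu <- ifelse(group == group_labels[1L], cq_mean - eff, cq_mean)
      vals <- rtnorm_below(n, mu, cq_sd, cq_cutoff)
      detected <- if (g %in% housekeeping) {
        !(cell_id %in% casualties)
      } else {
        stats::runif(n) >= dropout_prob
      }
      cq[detected, g] <- vals[detected]
    }
    if (n_low_quality_wells > 0) {
      det_idx <- which(!is.na(cq) & !(col(cq) %in% match(housekeeping, genes)))
      pick <- sample(det_idx, min(n_low_quality_wells, length(det_idx)))
      quality[pick] <- stats::runif(length(pick), 0, 0.5)
    }
    list(
      matrix = cq_matrix(cq, quality,
                         data.frame(cell_id = cell_id, mouse_id = mouse_id,
                                    group = group, stringsAsFactors = FALSE)),
      truth = ground_truth(
        "cq_matrix",
        params = list(n_cells_per_group = n_cells_per_group,
                      de_genes = de_genes, dropout_prob = dropout_prob,
                      cq_mean = cq_mean, cq_sd = cq_sd, cq_cutoff = cq_cutoff,
                      housekeeping = housekeeping, n_mice = n_mice),
        labels = list(de_genes = de_genes, qc_casualties = casualties),
        seed = seed)
    )
  })
}

#' Simulate a mouse-structured receptor-coexpression population
#'
#' Each mouse contributes `n_cells_per_mouse` cells whose receptor detection
#' pattern (neither / gene-a only / gene-b only / both) is drawn from the
#' designed class probabilities. Output feeds [classify_receptors()].
#'
#' @param n_mice Number of mice (default 3).
#' @param n_cells_per_mouse Cells per mouse (default 50).
#' @param class_probs Numeric length-4 probability vector for (neither,
#'   a-only, b-only, both); must sum to 1.
#' @param gene_a,gene_b Receptor gene names.
#' @param cq_mean,cq_sd,cq_cutoff Detected-Cq distribution parameters.
#' @param seed Integer seed.
#' @return List with `$matrix` ([cq_matrix()]) and `$truth`
#'   (`labels$class` per cell, `labels$class_probs`).
#' @export
gen_receptor_population <- function(n_mice = 3, n_cells_per_mouse = 50,
                                    class_probs = c(0.20, 0.60, 0.01, 0.19),
                                    gene_a = "Slc5a1", gene_b = "Tas1r3",
                                    cq_mean = 26, cq_sd = 0.8, cq_cutoff = 34,
                                    seed = 1) {
  stopifnot(length(class_probs) == 4L, all(class_probs >= 0))
  if (abs(sum(class_probs) - 1) > 1e-9) {
    stop("class_probs must sum to 1", call. = FALSE)
  }
  housekeeping <- c("Gapdh", "Actb1")
  genes <- c(housekeeping, gene_a, gene_b)
  lv <- c("neither", "a_only", "b_only", "both")
  n <- n_mice * n_cells_per_mouse
  cell_id <- sprintf("cell_%03d", seq_len(n))
  mouse_id <- rep(sprintf("mouse_%d", seq_len(n_mice)),
                  each = n_cells_per_mouse)
  local_seed(seed, {
    cls <- sample(lv, n, replace = TRUE, prob = class_probs)
    cq <- matrix(NA_real_, n, length(genes),
                 dimnames = list(cell_id, genes))
    for (g in housekeeping) cq[, g] <- rtnorm_below(n, cq_mean, cq_sd, cq_cutoff)
    det_a <- cls %in% c("a_only", "both")
    det_b <- cls %in% c("b_only", "both")
    cq[det_a, gene_a] <- rtnorm_below(sum(det_a), cq_mean, cq_sd, cq_cutoff)
    cq[det_b, gene_b] <- rtnorm_below(sum(det_b), cq_mean, cq_sd, cq_cutoff)
    quality <- matrix(stats::runif(n * length(genes), 0.7, 1), n,
                      length(genes), dimnames = list(cell_id, genes))
    list(
      matrix = cq_matrix(cq, quality,
                         data.frame(cell_id = cell_id, mouse_id = mouse_id,
                                    group = "GFP+", stringsAsFactors = FALSE)),
      truth = ground_truth(
        "receptor_population",
        params = list(n_mice = n_mice, n_cells_per_mouse = n_cells_per_mouse,
                      class_probs = class_probs, gene_a = gene_a,
                      gene_b = gene_b),
        labels = list(class = data.frame(cell_id = cell_id, class = cls,
                                         stringsAsFactors = FALSE),
                      class_probs = stats::setNames(class_probs, lv)),
        seed = seed)
    )
  })
}

#' Simulate a two-bottle intake session
#'
#' Cumulative 0.01-g-quantized intake streams for two bottles sampled every
#' `tick_s` seconds. The final intakes split `total_g` by `true_pref_frac`
#' exactly (to quantization); consumption events are spread uniformly over
#' the session. Transient negative sensor dips (reverting within one tick,
#' never on the final tick) are injected with probability `dip_prob` per
#' tick.
#'
#' @param true_pref_frac Designed sucrose preference in `[0, 1]`.
#' @param total_g Total liquid consumed over the session (>= 0).
#' @param tick_s Sensor period (default 5 s).
#' @param duration_min Session length (default 60 min).
#' @param dip_prob Per-tick probability of a transient negative dip.
#' @param dip_mag_g Dip magnitude in grams (default 0.05, > 0).
#' @param seed Integer seed.
#' @return List with `$sucrose`, `$sucralose` (raw [intake_stream()]s,
#'   channels `bottle_a`/`bottle_b`) and `$truth` (`labels$true_pref_pct`,
#'   `labels$sucrose_g`, `labels$sucralose_g`).
#' @export
gen_intake_session <- function(true_pref_frac, total_g, tick_s = 5,
                               duration_min = 60, dip_prob = 0,
                               dip_mag_g = 0.05, seed = 1) {
  stopifnot(true_pref_frac >= 0, true_pref_frac <= 1)
  if (total_g < 0) stop("total_g must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(dip_mag_g, "dip_mag_g")
  ts <- seq(0, duration_min * 60, by = tick_s)
  n <- length(ts)
  units_total <- round(total_g * 100)
  units_a <- round(units_total * true_pref_frac)
  units_b <- units_total - units_a

  local_seed(seed, {
    one_bottle <- function(units, channel) {
      counts <- integer(n)
      if (units > 0L) {
        at <- sample(2:n, units, replace = TRUE)
        tab <- tabulate(at, nbins = n)
        counts <- tab
      }
      cum_units <- cumsum(counts)
      raw_units <- cum_units
      dip_ticks <- integer(0)
      if (dip_prob > 0 && n > 2L) {
        cand <- 2:(n - 1L)
        hit <- cand[stats::runif(length(cand)) < dip_prob]
        # keep dips isolated so each reverts within one tick
        if (length(hit) > 1L) hit <- hit[c(TRUE, diff(hit) > 1L)]
        dip_ticks <- hit
        raw_units[hit] <- pmax(0L, cum_units[hit] - round(dip_mag_g * 100))
      }
      list(stream = intake_stream(ts, raw_units * 0.01, channel),
           final_g = cum_units[n] * 0.01, dip_ticks = dip_ticks)
    }
    a <- one_bottle(units_a, "bottle_a")
    b <- one_bottle(units_b, "bottle_b")
    list(
      sucrose = a$stream, sucralose = b$stream,
      truth = ground_truth(
        "intake_session",
        params = list(true_pref_frac = true_pref_frac, total_g = total_g,
                      tick_s = tick_s, duration_min = duration_min,
                      dip_prob = dip_prob, dip_mag_g = dip_mag_g),
        labels = list(
          true_pref_pct = if (units_total > 0)
            100 * units_a / units_total else NA_real_,
          sucrose_g = a$final_g, sucralose_g = b$final_g,
          dip_ticks = list(sucrose = a$dip_ticks, sucralose = b$dip_ticks)),
        seed = seed)
    )
  })
}

#' Simulate a fiber cut-back transmission series
#'
#' `P(L) = p0 * 10^(-alpha (L - L_min) / 10)` with multiplicative lognormal
#' noise of mean 1 and the stated coefficient of variation.
#'
#' @param alpha_db_per_cm True attenuation coefficient (>= 0).
#' @param lengths_cm Strictly increasing fiber lengths (>= 2).
#' @param p0_mw Output power at the shortest length (default 1 mW).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives a noiseless series).
#' @param geometry Passed to [cutback_series()].
#' @param seed Integer seed.
#' @return List with `$series` ([cutback_series()]) and `$truth`
#'   (`labels$alpha_db_per_cm`).
#' @export
gen_cutback <- function(alpha_db_per_cm, lengths_cm, p0_mw = 1,
                        noise_cv = 0, geometry = "straight", seed = 1) {
  stopifnot(alpha_db_per_cm >= 0)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (length(lengths_cm) < 2L || is.unsorted(lengths_cm, strictly = TRUE)) {
    stop("lengths must be strictly increasing with >= 2 values", call. = FALSE)
  }
  stop_if_not_scalar_pos(p0_mw, "p0_mw")
  local_seed(seed, {
    p <- p0_mw * 10^(-alpha_db_per_cm * (lengths_cm - lengths_cm[1L]) / 10)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      p <- p * stats::rlnorm(length(p), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    list(
      series = cutback_series(lengths_cm, p, geometry = geometry),
      truth = ground_truth(
        "cutback",
        params = list(alpha_db_per_cm = alpha_db_per_cm,
                      lengths_cm = lengths_cm, p0_mw = p0_mw,
                      noise_cv = noise_cv),
        labels = list(alpha_db_per_cm = alpha_db_per_cm), seed = seed)
    )
  })
}
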