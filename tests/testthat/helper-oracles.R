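# Independent oracles used to cross-check package computations. These are
# deliberately written as naive scans / closed forms, not as calls into the
# code paths they validate.

# Sample-by-sample threshold-crossing scan: state machine over the trace,
# recording the absolute extremum of each supra-threshold excursion and
# merging events closer than the refractory period (larger extremum wins).
oracle_spike_scan <- function(v, fs, k, refractory_s) {
  thr <- k * sqrt(mean(v^2))
  times <- numeric(0)
  amps <- numeric(0)
  in_exc <- FALSE
  best_i <- 0L
  best_a <- -Inf
  for (i in seq_along(v)) {
    if (abs(v[i]) > thr) {
      if (!in_exc) {
        in_exc <- TRUE
        best_i <- i
        best_a <- abs(v[i])
      } else if (abs(v[i]) > best_a) {
        best_i <- i
        best_a <- abs(v[i])
      }
    } else if (in_exc) {
      in_exc <- FALSE
      times <- c(times, (best_i - 1) / fs)
      amps <- c(amps, best_a)
    }
  }
  if (in_exc) {
    times <- c(times, (best_i - 1) / fs)
    amps <- c(amps, best_a)
  }
  if (length(times) > 1) {
    out_t <- times[1]
    out_a <- amps[1]
    for (i in 2:length(times)) {
      last <- length(out_t)
      if (times[i] - out_t[last] < refractory_s) {
        if (amps[i] > out_a[last]) {
          out_t[last] <- times[i]
          out_a[last] <- amps[i]
        }
      } else {
        out_t <- c(out_t, times[i])
        out_a <- c(out_a, amps[i])
      }
    }
    times <- out_t
  }
  times
}

# Full direct convolution: dense outer sum of Gaussians, no truncation.
oracle_rate_convolution <- function(spike_times, centers, sigma) {
  if (!length(spike_times)) return(numeric(length(centers)))
  colSums(outer(spike_times, centers,
                function(s, t) stats::dnorm(t, mean = s, sd = sigma)))
}

# Textbook Benjamini-Hochberg: sort, adjust by n/rank, running minimum from
# the largest p down, restore input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- n / seq_len(n) * p[o]
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

rnorm_fixed <- function(n, sd, seed) {
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

# Build a firing_rate_series by hand (for constructed-profile tests).
make_rate_series <- function(centers, rate, bin_width = 0.2, sigma = 0.2) {
  structure(list(bin_centers = centers, rate = rate, bin_width = bin_width,
                 kernel_sigma = sigma),
            class = "firing_rate_series")
}
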