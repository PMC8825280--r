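# Fiber-optic cut-back attenuation analysis and the small closed-form
# physiology computations used across the study (gallbladder and gastric
# emptying, membrane capacitance, plate-reader glutamate quantification).

#' Construct a cut-back transmission series
#'
#' @param lengths_cm Strictly increasing fiber lengths in cm (>= 2 values).
#' @param output_power Measured output power at each length (mW or percent
#'   of the shortest-length output; only ratios matter). Must be positive.
#' @param geometry `"straight"` or `"bent"`.
#' @param bend_radius_mm,bend_angle_deg Bend geometry (bent fibers only).
#' @return An object of class `cutback_series`.
#' @export
cutback_series <- function(lengths_cm, output_power,
                           geometry = c("straight", "bent"),
                           bend_radius_mm = NA_real_,
                           bend_angle_deg = NA_real_) {
  geometry <- match.arg(geometry)
  stopifnot(length(lengths_cm) == length(output_power))
  if (length(lengths_cm) < 2L) stop("need at least 2 lengths", call. = FALSE)
  if (is.unsorted(lengths_cm, strictly = TRUE)) {
    stop("lengths must be strictly increasing", call. = FALSE)
  }
  if (any(output_power <= 0)) stop("non-positive output power", call. = FALSE)
  structure(list(lengths_cm = as.numeric(lengths_cm),
                 output_power = as.numeric(output_power),
                 geometry = geometry, bend_radius_mm = bend_radius_mm,
                 bend_angle_deg = bend_angle_deg),
            class = "cutback_series")
}

#' Fit the cut-back loss coefficient
#'
#' Converts each power to attenuation relative to the shortest length,
#' `A(L) = -10 log10(P(L) / P(L_min))` dB, and fits `A ~ (L - L_min)` by
#' ordinary least squares. The slope is the loss coefficient alpha in
#' dB/cm. Only power ratios enter, so the fit is invariant to a uniform
#' rescaling of all powers.
#'
#' @param series A [cutback_series()].
#' @return An object of class `loss_fit`: `$alpha_db_per_cm`,
#'   `$intercept_db`, `$residuals`, `$n_points`, `$geometry`.
#' @export
fit_loss <- function(series) {
  stopifnot(inherits(series, "cutback_series"))
  dl <- series$lengths_cm - series$lengths_cm[1L]
  atten <- -10 * log10(series$output_power / series$output_power[1L])
  fit <- stats::lm(atten ~ dl)
  structure(
    list(alpha_db_per_cm = unname(stats::coef(fit)[2L]),
         intercept_db = unname(stats::coef(fit)[1L]),
         residuals = unname(stats::residuals(fit)),
         n_points = length(dl),
         geometry = series$geometry),
    class = "loss_fit"
  )
}

#' @export
print.loss_fit <- function(x, ...) {
  cat(sprintf("<loss_fit> alpha = %.3f dB/cm (%s fiber, %d points)\n",
              x$alpha_db_per_cm, x$geometry, x$n_points))
  invisible(x)
}

#' Bent-fiber transmission as a percentage of the straight fiber
#'
#' @param straight_mw,bent_mw Output powers (mW) for the straight and bent
#'   configurations.
#' @return `100 * bent_mw / straight_mw`.
#' @export
bend_transmission <- function(straight_mw, bent_mw) {
  if (any(straight_mw <= 0)) stop("straight power must be positive", call. = FALSE)
  100 * bent_mw / straight_mw
}

#' Optical power density at the fiber tip
#'
#' Power divided by the core cross-sectional area (the reference area for
#' the reported tip intensity).
#'
#' @param power_mw Output power in mW.
#' @param core_diameter_um Core diameter in micrometers (default 230, the
#'   drawn polymer fiber).
#' @return Power density in mW/mm^2.
#' @export
power_density <- function(power_mw, core_diameter_um = 230) {
  stop_if_not_scalar_pos(core_diameter_um, "core_diameter_um")
  d_mm <- core_diameter_um / 1000
  power_mw / (pi * (d_mm / 2)^2)
}

#' Ellipsoid gallbladder volume from caliper measurements
#'
#' `V (ul) = length (mm) x width (mm) x depth (mm) x pi / 6`.
#'
#' @param length_mm,width_mm,depth_mm Caliper measurements in mm.
#' @return Volume in microliters.
#' @export
gallbladder_volume <- function(length_mm, width_mm, depth_mm) {
  if (any(c(length_mm, width_mm, depth_mm) <= 0)) {
    stop("dimensions must be positive", call. = FALSE)
  }
  length_mm * width_mm * depth_mm * pi / 6
}

#' Gallbladder emptying as percent volume change
#'
#' @param pre_ul,post_ul Pre- and post-infusion volumes (ul); `pre_ul > 0`.
#' @return `100 * (pre - post) / pre`.
#' @export
emptying_pct <- function(pre_ul, post_ul) {
  if (any(pre_ul <= 0)) stop("pre-infusion volume must be positive", call. = FALSE)
  100 * (pre_ul - post_ul) / pre_ul
}

#' Gastric emptying as percent volume remaining
#'
#' @param pre_g,post_g Stomach weights before and after desiccation-based
#'   measurement (g); `pre_g > 0`.
#' @return `100 * post_g / pre_g`.
#' @export
gastric_emptying_pct <- function(pre_g, post_g) {
  if (any(pre_g <= 0)) stop("pre-weight must be positive", call. = FALSE)
  100 * post_g / pre_g
}

#' Membrane capacitance from the current transient
#'
#' `C_m = tau * I_0 / dE`; with tau in ms, I_0 in pA and dE in mV the
#' result is in pF.
#'
#' @param tau_ms Decay time constant of the current transient (ms).
#' @param i0_pa Current transient relative to the prepulse potential (pA).
#' @param de_mv Voltage step (mV, nonzero).
#' @return Capacitance in pF.
#' @export
membrane_capacitance <- function(tau_ms, i0_pa, de_mv) {
  if (any(de_mv == 0)) stop("voltage step must be nonzero", call. = FALSE)
  tau_ms * i0_pa / de_mv
}

#' Capacitance-normalized maximal current
#'
#' @param i_max_pa Maximal current (pA).
#' @param cm_pf Membrane capacitance (pF, > 0).
#' @return Current density in pA/pF.
#' @export
normalized_current <- function(i_max_pa, cm_pf) {
  if (any(cm_pf <= 0)) stop("capacitance must be positive", call. = FALSE)
  i_max_pa / cm_pf
}

#' Glutamate concentration from plate-reader absorbances
#'
#' Per well, the mean of the (typically nine) absorbance reads is corrected
#' by subtracting the mean control absorbance, then interpolated on a
#' least-squares linear standard curve fit to the provided
#' (concentration, absorbance) standards.
#'
#' @param sample_reads Numeric vector of reads for one well, or a list of
#'   such vectors (e.g. a triplicate).
#' @param control_reads Numeric vector of reads for the no-enzyme control.
#' @param standards Data frame or 2-column matrix of `(concentration,
#'   absorbance)` standard points (>= 2 distinct absorbances).
#' @return Data frame with one row per well: `corrected_absorbance`,
#'   `concentration`, `extrapolated` (flag for corrected absorbances outside
#'   the standard range); attribute `triplicate_mean` holds the mean
#'   concentration across wells.
#' @export
glutamate_concentration <- function(sample_reads, control_reads, standards) {
  if (is.numeric(sample_reads)) sample_reads <- list(sample_reads)
  std <- as.data.frame(standards)
  names(std)[1:2] <- c("concentration", "absorbance")
  if (nrow(std) < 2L || length(unique(std$absorbance)) < 2L) {
    stop("need >= 2 standards with distinct absorbances", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration, data = std)
  slope <- stats::coef(fit)[["concentration"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  if (slope == 0) stop("degenerate standard curve (zero slope)", call. = FALSE)
  ctrl <- mean(control_reads)
  rng <- range(std$absorbance)
  out <- do.call(rbind, lapply(seq_along(sample_reads), function(i) {
    corr <- mean(sample_reads[[i]]) - ctrl
    data.frame(well = i, corrected_absorbance = corr,
               concentration = (corr - intercept) / slope,
               extrapolated = corr < rng[1L] | corr > rng[2L])
  }))
  attr(out, "triplicate_mean") <- mean(out$concentration)
  out
}
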