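# Component response functions of the per-mechanism sensitivity model:
# temporal channels, spatial log-parabolas, spatial summation, luminance
# gain, and eccentricity attenuation. All are vectorised over the stimulus
# arguments.

# Smallest spatial frequency at which a Gabor is evaluated; a nominal 0-cpd
# Gaussian blob is mapped to a half-cycle Gabor before this floor applies.
.rho_min <- 1e-4
# Floor on the transient peak frequency: the peak-vs-log-luminance line is
# linear and can go negative far below the fitted luminance range.
.omega0_floor <- 0.1

#' Sustained temporal channel response
#'
#' Generalised-exponential low-pass filter `exp(-omega^beta / sigma)`.
#' Equal to 1 at 0 Hz and strictly decreasing.
#'
#' @param omega temporal frequency in Hz, >= 0 (vectorised).
#' @param channel parameter sublist with elements `beta`, `sigma` (e.g.
#'   `params$ach$sustained`).
#' @return response in (0, 1].
#' @export
sustained_response <- function(omega, channel) {
  if (any(omega < 0)) stop("temporal frequency must be >= 0")
  exp(-(omega^channel$beta) / channel$sigma)
}

#' Peak frequency of the transient channel as a function of luminance
#'
#' `omega0(Y) = m_omega * log10(Y) + c_omega` Hz, floored at 0.1 Hz so the
#' band-pass filter stays well defined at extremely low luminance.
#'
#' @param Y mean luminance in cd/m^2, > 0 (vectorised).
#' @param channel parameter sublist with `m_omega`, `c_omega`
#'   (`params$ach$transient`).
#' @return peak temporal frequency in Hz.
#' @export
transient_peak <- function(Y, channel) {
  if (any(Y <= 0)) stop("luminance must be > 0")
  pmax(channel$m_omega * log10(Y) + channel$c_omega, .omega0_floor)
}

#' Transient temporal channel response
#'
#' Band-pass filter `exp(-(omega^beta - omega0(Y)^beta)^2 / sigma)`,
#' maximised (= 1) at `omega = omega0(Y)`; the peak shifts towards higher
#' frequencies as luminance increases when `m_omega > 0`.
#'
#' @param omega temporal frequency in Hz, >= 0 (vectorised).
#' @param Y mean luminance in cd/m^2, > 0.
#' @param channel parameter sublist with `beta`, `sigma`, `m_omega`,
#'   `c_omega`.
#' @return response in (0, 1].
#' @export
transient_response <- function(omega, Y, channel) {
  if (any(omega < 0)) stop("temporal frequency must be >= 0")
  w0 <- transient_peak(Y, channel)
  exp(-((omega^channel$beta - w0^channel$beta)^2) / channel$sigma)
}

#' Log-parabola spatial tuning curve
#'
#' `10^(-(log10(rho) - log10(rho_m))^2 / den)` where the bandwidth
#' denominator is `2^k_b` (`bandwidth_mode = "pow2"`, the default, strictly
#' positive for any real k_b) or `2 * k_b^2` (`"sq"`, an alternative
#' parameterisation kept for comparison). Equals 1 at the peak and is
#' symmetric about it on a log-frequency axis.
#'
#' @param rho spatial frequency in cpd, > 0 (vectorised).
#' @param rho_m peak frequency in cpd, > 0.
#' @param k_b bandwidth parameter.
#' @param bandwidth_mode `"pow2"` or `"sq"`.
#' @return response in (0, 1].
#' @export
log_parabola <- function(rho, rho_m, k_b, bandwidth_mode = "pow2") {
  if (any(rho <= 0)) stop("spatial frequency must be > 0")
  den <- switch(bandwidth_mode,
                pow2 = 2^k_b,
                sq = 2 * k_b^2,
                stop("unknown bandwidth_mode: ", bandwidth_mode))
  10^(-((log10(rho) - log10(rho_m))^2) / den)
}

#' Achromatic spatial envelope (truncated log-parabola)
#'
#' The log-parabola truncated on the low-frequency side: below the peak,
#' once the parabola falls under `1 - k_a` the response is held at that
#' plateau, producing the band-pass shape of static achromatic sensitivity.
#' Above the peak it is the plain parabola.
#'
#' @param rho spatial frequency in cpd, > 0 (vectorised).
#' @param rho_m peak frequency in cpd.
#' @param k_b bandwidth parameter.
#' @param k_a truncation depth in (0, 1).
#' @inheritParams log_parabola
#' @return response in (0, 1].
#' @export
spatial_envelope_achromatic <- function(rho, rho_m, k_b, k_a,
                                        bandwidth_mode = "pow2") {
  lp <- log_parabola(rho, rho_m, k_b, bandwidth_mode)
  plateau <- 1 - k_a
  ifelse(rho < rho_m & lp < plateau, plateau, lp)
}

#' Chromatic spatial envelope (low-pass truncated log-parabola)
#'
#' Equal to 1 for all frequencies below the peak and to the log-parabola
#' above it; continuous at the peak.
#'
#' @inheritParams spatial_envelope_achromatic
#' @return response in (0, 1].
#' @export
spatial_envelope_chromatic <- function(rho, rho_m, k_b,
                                       bandwidth_mode = "pow2") {
  lp <- log_parabola(rho, rho_m, k_b, bandwidth_mode)
  ifelse(rho < rho_m, 1, lp)
}

#' Critical summation area
#'
#' `a_x(rho) = a0 / (1 + (rho / rho0)^2)` in deg^2: the area up to which
#' sensitivity grows with stimulus size. Maximal (`a0`) at 0 cpd and
#' decreasing with spatial frequency.
#'
#' @param rho spatial frequency in cpd, >= 0 (vectorised).
#' @param channel parameter sublist with `a0` (deg^2), `rho0` (cpd).
#' @return critical area in deg^2, in (0, a0].
#' @export
critical_area <- function(rho, channel) {
  if (any(rho < 0)) stop("spatial frequency must be >= 0")
  channel$a0 / (1 + (rho / channel$rho0)^2)
}

#' Area-dependent sensitivity factor
#'
#' `S_area = rho * sqrt(a_x / (1 + a_x / a))` in cycles: grows with stimulus
#' area `a` and saturates at the critical number of cycles `rho * sqrt(a_x)`.
#'
#' @param rho spatial frequency in cpd, > 0 (vectorised).
#' @param area stimulus area in deg^2, > 0.
#' @param channel parameter sublist with `a0`, `rho0`.
#' @return sensitivity factor in cycles.
#' @export
area_sensitivity <- function(rho, area, channel) {
  if (any(area <= 0)) stop("area must be > 0")
  ax <- critical_area(rho, channel)
  rho * sqrt(ax / (1 + ax / area))
}

#' Luminance-dependent gain factors
#'
#' Achromatic sustained: `ks1 * (1 + ks2/Y)^(-ks3) * (1 - (1 + ks4/Y)^(-ks5))`
#' -- a DeVries-Rose rise, a Weber plateau, and a decline at very high
#' luminance. Chromatic sustained: `ks1 * (1 + ks2/Y)^(-ks3)` -- rise and
#' saturation at asymptote `ks1`. Achromatic transient:
#' `ks2 * Y^ks1` -- a power law, linear in log-log coordinates.
#'
#' @param Y mean luminance in cd/m^2, > 0 (vectorised).
#' @param channel parameter sublist with the relevant `ks*` entries.
#' @return nonnegative gain.
#' @export
luminance_gain_ach_sustained <- function(Y, channel) {
  if (any(Y <= 0)) stop("luminance must be > 0")
  channel$ks1 * (1 + channel$ks2 / Y)^(-channel$ks3) *
    (1 - (1 + channel$ks4 / Y)^(-channel$ks5))
}

#' @rdname luminance_gain_ach_sustained
#' @export
luminance_gain_chromatic <- function(Y, channel) {
  if (any(Y <= 0)) stop("luminance must be > 0")
  channel$ks1 * (1 + channel$ks2 / Y)^(-channel$ks3)
}

#' @rdname luminance_gain_ach_sustained
#' @export
luminance_gain_transient <- function(Y, channel) {
  if (any(Y <= 0)) stop("luminance must be > 0")
  channel$ks2 * Y^channel$ks1
}

#' Peak spatial frequency as a function of luminance
#'
#' For the achromatic sustained channel the log-parabola peak shifts with
#' luminance: `rho_m(Y) = k_rho1 * (1 + k_rho2/Y)^(-k_rho3)` (increasing,
#' asymptote `k_rho1`). The achromatic transient and the two chromatic
#' peaks are luminance-independent constants (`k_rho`).
#'
#' @param Y mean luminance in cd/m^2, > 0 (vectorised).
#' @param channel parameter sublist (`params$<mech>$<channel>`).
#' @return peak spatial frequency in cpd.
#' @export
peak_frequency <- function(Y, channel) {
  if (any(Y <= 0)) stop("luminance must be > 0")
  if (!is.null(channel$k_rho1)) {
    channel$k_rho1 * (1 + channel$k_rho2 / Y)^(-channel$k_rho3)
  } else {
    rep_len(channel$k_rho, length(Y))
  }
}

#' Eccentricity coefficients blended across the visual field
#'
#' The attenuation coefficients are a linear blend of nasal and non-nasal
#' values with weight `alpha = min(1, |theta - 180| / 90)`: pure nasal
#' coefficients at `theta = 180`, pure non-nasal for `|theta - 180| >= 90`
#' (including the temporal meridian `theta = 0`). Right-eye convention.
#'
#' @param theta visual-field angle in degrees, in \[0, 360).
#' @param ecc_pars parameter sublist with `ke1`, `ke2`, `ke1_nasal`,
#'   `ke2_nasal` (e.g. `params$ach$ecc`).
#' @return list with vectors `ke1`, `ke2`.
#' @export
eccentricity_weights <- function(theta, ecc_pars) {
  if (any(theta < 0 | theta >= 360))
    stop("visual-field angle must lie in [0, 360)")
  alpha <- pmin(1, abs(theta - 180) / 90)
  list(ke1 = alpha * ecc_pars$ke1 + (1 - alpha) * ecc_pars$ke1_nasal,
       ke2 = alpha * ecc_pars$ke2 + (1 - alpha) * ecc_pars$ke2_nasal)
}

#' Eccentricity-dependent attenuation
#'
#' `S_ecc = 10^(-(ke1 * rho * e + ke2 * e))`: log-linear in eccentricity,
#' with a steeper decline at higher spatial frequency when `ke1 > 0`.
#' Equals 1 in the fovea (`e = 0`).
#'
#' @param ecc retinal eccentricity in degrees, >= 0 (vectorised).
#' @param rho spatial frequency in cpd, >= 0.
#' @param theta visual-field angle in degrees (see
#'   [eccentricity_weights()]).
#' @param ecc_pars parameter sublist with the four `ke*` coefficients.
#' @return attenuation factor in (0, 1].
#' @export
eccentricity_attenuation <- function(ecc, rho, theta, ecc_pars) {
  if (any(ecc < 0)) stop("eccentricity must be >= 0")
  if (any(rho < 0)) stop("spatial frequency must be >= 0")
  w <- eccentricity_weights(theta, ecc_pars)
  10^(-(w$ke1 * rho * ecc + w$ke2 * ecc))
}
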