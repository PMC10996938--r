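# Per-mechanism sensitivity: the combination of temporal, spatial, area,
# luminance and eccentricity factors for the achromatic (sustained +
# transient), red-green and yellow-violet mechanisms.

# Saliency-style combined factor for one temporal channel of one mechanism:
# luminance gain x area factor x spatial envelope.
.sal <- function(rho, area, Y, channel, achromatic, transient, bw_mode) {
  gain <- if (transient) {
    luminance_gain_transient(Y, channel)
  } else if (achromatic) {
    luminance_gain_ach_sustained(Y, channel)
  } else {
    luminance_gain_chromatic(Y, channel)
  }
  rho_m <- peak_frequency(Y, channel)
  env <- if (achromatic) {
    spatial_envelope_achromatic(rho, rho_m, channel$k_b, channel$k_a, bw_mode)
  } else {
    spatial_envelope_chromatic(rho, rho_m, channel$k_b, bw_mode)
  }
  gain * area_sensitivity(rho, area, channel) * env
}

# Vectorised mechanism sensitivity over plain numeric stimulus vectors
# (recycled to a common length). `rho` must already be the effective Gabor
# frequency (> 0).
.mech_sensitivity <- function(mech, rho, omega, Y, area, ecc, theta, params) {
  n <- max(length(rho), length(omega), length(Y), length(area),
           length(ecc), length(theta))
  rho <- rep_len(rho, n);   omega <- rep_len(omega, n)
  Y <- rep_len(Y, n);       area <- rep_len(area, n)
  ecc <- rep_len(ecc, n);   theta <- rep_len(theta, n)
  bw <- params$options$bandwidth_mode
  m <- params[[mech]]
  s_ecc <- eccentricity_attenuation(ecc, rho, theta, m$ecc)
  if (mech == "ach") {
    # Both temporal branches are always evaluated, including omega = 0; the
    # transient contribution at 0 Hz is whatever the band-pass filter yields.
    sus <- sustained_response(omega, m$sustained) *
      .sal(rho, area, Y, m$sustained, achromatic = TRUE,
           transient = FALSE, bw_mode = bw)
    tra <- transient_response(omega, Y, m$transient) *
      .sal(rho, area, Y, m$transient, achromatic = TRUE,
           transient = TRUE, bw_mode = bw)
    s_ecc * sus + s_ecc * tra
  } else {
    s_ecc * sustained_response(omega, m$sustained) *
      .sal(rho, area, Y, m$sustained, achromatic = FALSE,
           transient = FALSE, bw_mode = bw)
  }
}

#' Sensitivity of one opponent mechanism to a Gabor stimulus
#'
#' Combines eccentricity attenuation, temporal channel response(s) and the
#' luminance-gain x area x spatial-envelope product. The achromatic
#' mechanism is the sum of its sustained and transient branches (both always
#' evaluated, including at 0 Hz); the chromatic mechanisms have a single
#' sustained branch.
#'
#' @param spec a [csf_stimulus()] (its `dir` and `bg` chromaticity are not
#'   used here beyond the background luminance `Y = L0 + M0`).
#' @param params a [csf_params()] object.
#' @param mech `"ach"`, `"rg"` or `"yv"`.
#' @return positive scalar sensitivity of the mechanism.
#' @export
mechanism_sensitivity <- function(spec, params, mech = c("ach", "rg", "yv")) {
  mech <- match.arg(mech)
  params <- csf_params(params)
  stopifnot(inherits(spec, "csf_stimulus"))
  Y <- spec$bg[1] + spec$bg[2]
  rho <- if (spec$shape == "disc") NA_real_ else
    .effective_rho(spec$rho, spec$area)
  if (spec$shape == "disc")
    stop("mechanism_sensitivity is defined for Gabor stimuli; ",
         "use disc_mechanism_sensitivity for discs")
  .mech_sensitivity(mech, rho, spec$omega, Y, spec$area, spec$ecc,
                    spec$theta, params)
}

# Log-spaced frequency grid over which the disc extension maximises the
# Gabor sensitivity: 2^-6 .. 2^6 cpd, 257 points. The maximand is smooth
# and unimodal for sensible parameters, so no refinement is needed.
.disc_rho_grid <- 2^seq(-6, 6, length.out = 257)

#' Sensitivity of one opponent mechanism to a disc stimulus
#'
#' A disc forms a circular edge, detected by the most sensitive spatial
#' channel: `S_disc = (2 * pi * a)^(1/beta) * max_rho S(rho, omega, Y,
#' a_disc, e)`, where the maximum of the Gabor mechanism sensitivity is
#' taken over a log grid of spatial frequencies at the fixed reference area
#' `a_disc`, and `beta = 3.01142`, `a_disc = 2.42437` deg^2 are fixed
#' (never fitted) constants.
#'
#' @param spec a [csf_stimulus()] with `shape = "disc"`.
#' @param params a [csf_params()] object.
#' @param mech `"ach"`, `"rg"` or `"yv"`.
#' @return positive scalar disc sensitivity of the mechanism.
#' @export
disc_mechanism_sensitivity <- function(spec, params,
                                       mech = c("ach", "rg", "yv")) {
  mech <- match.arg(mech)
  params <- csf_params(params)
  stopifnot(inherits(spec, "csf_stimulus"))
  if (spec$shape != "disc") stop("stimulus shape must be 'disc'")
  Y <- spec$bg[1] + spec$bg[2]
  smax <- max(.mech_sensitivity(mech, .disc_rho_grid, spec$omega, Y,
                                params$disc$a_disc, spec$ecc, spec$theta,
                                params))
  (2 * pi * spec$area)^(1 / params$disc$beta) * smax
}
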