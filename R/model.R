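# Pooling of mechanism-weighted opponent contrasts into detection energy,
# inversion to threshold, and sensitivity in inverse-cone-contrast units.

# sqrt(sum((d/bg)^2)) with 0/0 treated as 0; a nonzero increment on a zero
# background component is an error (cone contrast undefined there).
.cc_raw <- function(d, bg) {
  r2 <- ifelse(d == 0, 0, (d / bg)^2)
  if (any(!is.finite(r2)))
    stop("nonzero increment on a zero background cone component")
  sqrt(sum(r2))
}

# Per-mechanism sensitivities for a stimulus, dispatching on shape.
.spec_mech_sens <- function(spec, params) {
  if (spec$shape == "disc") {
    c(ach = disc_mechanism_sensitivity(spec, params, "ach"),
      rg = disc_mechanism_sensitivity(spec, params, "rg"),
      yv = disc_mechanism_sensitivity(spec, params, "yv"))
  } else {
    c(ach = mechanism_sensitivity(spec, params, "ach"),
      rg = mechanism_sensitivity(spec, params, "rg"),
      yv = mechanism_sensitivity(spec, params, "yv"))
  }
}

#' Contrast energy of a stimulus
#'
#' Opponent contrasts of the modulation direction are weighted by the
#' per-mechanism sensitivities and pooled with a Euclidean norm:
#' `E = sqrt(sum_c (S_c * C_c)^2)`. The root makes E homogeneous of degree
#' one in the modulation direction, which is what allows the detection
#' threshold (at `E = 1`) to be found analytically by rescaling. Detection
#' is assumed at `E = 1`.
#'
#' @param spec a [csf_stimulus()].
#' @param params a [csf_params()] object.
#' @return nonnegative scalar energy.
#' @export
contrast_energy <- function(spec, params) {
  stopifnot(inherits(spec, "csf_stimulus"))
  S <- .spec_mech_sens(spec, params)
  C <- opponent_contrast(lms_to_opponent(spec$dir), spec$bg)
  sqrt(sum((S * C)^2))
}

#' Model sensitivity: inverse cone contrast at the detection threshold
#'
#' The modulation direction scaled by `1/E` sits exactly at threshold
#' (`E = 1`), so the sensitivity is the inverse cone contrast of that
#' threshold increment:
#' `S = E * sqrt(3) / sqrt((dL/L0)^2 + (dM/M0)^2 + (dS/S0)^2)`.
#' The result is invariant to the magnitude of `dir`.
#'
#' @inheritParams contrast_energy
#' @return positive scalar sensitivity.
#' @examples
#' st <- csf_stimulus(bg = 30, dir = c(1, 1, 0), rho = 4, area = pi)
#' csf_sensitivity(st, default_params())
#' @export
csf_sensitivity <- function(spec, params) {
  stopifnot(inherits(spec, "csf_stimulus"))
  E <- contrast_energy(spec, params)
  if (!is.finite(E) || E <= 0)
    stop("contrast energy is not positive; cannot invert to a threshold")
  E * sqrt(3) / .cc_raw(spec$dir, spec$bg)
}

#' Sensitivity of a disc stimulus
#'
#' Convenience wrapper: [csf_sensitivity()] for a spec with
#' `shape = "disc"` (errors otherwise). Disc sensitivities scale with area
#' as `a^(1/beta)` and are independent of any nominal spatial frequency.
#'
#' @inheritParams contrast_energy
#' @return positive scalar sensitivity.
#' @export
disc_sensitivity <- function(spec, params) {
  stopifnot(inherits(spec, "csf_stimulus"))
  if (spec$shape != "disc") stop("stimulus shape must be 'disc'")
  csf_sensitivity(spec, params)
}

#' Full detection result for a stimulus
#'
#' @inheritParams contrast_energy
#' @return list of class `csf_detection` with elements `energy`,
#'   `sensitivity`, and `threshold_increment` (the cone increment `dir / E`,
#'   at which re-evaluated energy equals 1).
#' @export
csf_detect <- function(spec, params) {
  E <- contrast_energy(spec, params)
  structure(list(energy = E,
                 sensitivity = csf_sensitivity(spec, params),
                 threshold_increment = spec$dir / E),
            class = "csf_detection")
}

#' @export
print.csf_detection <- function(x, ...) {
  cat(sprintf("<csf_detection> energy = %.6g, sensitivity = %.6g\n",
              x$energy, x$sensitivity))
  invisible(x)
}

#' Predict sensitivities for a measurement table
#'
#' Vectorised model prediction over a record table in the measurement
#' schema (see [read_measurements()]): one predicted sensitivity per row,
#' Gabor and disc rows dispatched to their respective models.
#'
#' @param records data.frame in the measurement schema.
#' @param params a [csf_params()] object.
#' @return numeric vector of predicted sensitivities.
#' @export
csf_predict <- function(records, params) {
  params <- csf_params(params)
  .check_schema(records)
  n <- nrow(records)
  if (n == 0L) return(numeric(0))
  L0 <- records$L0; M0 <- records$M0; S0 <- records$S0
  if (any(L0 + M0 <= 0)) stop("background luminance L0 + M0 must be > 0")
  Y <- L0 + M0
  d <- rbind(records$dL, records$dM, records$dS)
  if (any(colSums(d != 0) == 0))
    stop("modulation direction must not be all zero")
  C <- (.dkl_matrix %*% d) / rep(Y, each = 3)       # 3 x n opponent contrasts
  S <- matrix(0, 3, n, dimnames = list(c("ach", "rg", "yv"), NULL))
  gab <- records$shape != "disc"
  if (any(gab)) {
    rho <- .effective_rho(records$rho_cpd[gab], records$area_deg2[gab])
    for (m in rownames(S))
      S[m, gab] <- .mech_sensitivity(m, rho, records$omega_hz[gab], Y[gab],
                                     records$area_deg2[gab],
                                     records$ecc_deg[gab],
                                     records$theta_deg[gab], params)
  }
  if (any(!gab)) {
    idx <- which(!gab)
    k <- length(.disc_rho_grid)
    # expand the frequency grid against the disc rows and take per-row maxima
    for (m in rownames(S)) {
      v <- .mech_sensitivity(m,
                             rep(.disc_rho_grid, times = length(idx)),
                             rep(records$omega_hz[idx], each = k),
                             rep(Y[idx], each = k),
                             params$disc$a_disc,
                             rep(records$ecc_deg[idx], each = k),
                             rep(records$theta_deg[idx], each = k),
                             params)
      mx <- matrix(v, nrow = k)
      S[m, idx] <- (2 * pi * records$area_deg2[idx])^(1 / params$disc$beta) *
        apply(mx, 2L, max)
    }
  }
  E <- sqrt(colSums((S * C)^2))
  sq <- function(d, b) ifelse(d == 0, 0, (d / b)^2)
  cc2 <- sq(records$dL, L0) + sq(records$dM, M0) + sq(records$dS, S0)
  if (any(!is.finite(cc2)))
    stop("nonzero increment on a zero background cone component")
  E * sqrt(3) / sqrt(cc2)
}
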