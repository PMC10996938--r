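# Stimulus specification: one detection stimulus (background, modulation
# direction, spatial/temporal frequency, area, eccentricity, shape).

#' Specify a detection stimulus
#'
#' @param bg background: either cone excitations `(L0, M0, S0)` or a single
#'   positive number, interpreted as the luminance of a D65-like grey
#'   background (routed through [d65_background()]).
#' @param dir modulation direction as cone-excitation increments
#'   `(dL, dM, dS)`, not all zero. All model sensitivities are invariant to
#'   the magnitude of this vector.
#' @param rho spatial frequency in cpd (Gabor stimuli). A value of 0 denotes
#'   a Gaussian blob, which is treated as a Gabor with half a sinusoidal
#'   cycle visible: `rho = 0.5 / (2 * sqrt(area / pi))`. Ignored for discs
#'   (with a warning if supplied).
#' @param omega temporal frequency in Hz, >= 0.
#' @param area stimulus area in deg^2 (`pi * sigma^2` for a Gabor with
#'   Gaussian envelope sigma), > 0.
#' @param ecc retinal eccentricity in degrees, >= 0.
#' @param theta visual-field angle in degrees, \[0, 360), right-eye
#'   convention (0 = temporal, 180 = nasal). Defaults to 0 when unspecified;
#'   irrelevant at `ecc = 0`.
#' @param shape `"gabor"` or `"disc"`.
#' @return object of class `csf_stimulus`.
#' @examples
#' csf_stimulus(bg = 100, dir = c(1, 1, 0), rho = 4, area = pi)
#' @export
csf_stimulus <- function(bg, dir, rho = NULL, omega = 0, area = 1,
                         ecc = 0, theta = NULL, shape = c("gabor", "disc")) {
  shape <- match.arg(shape)
  if (is.numeric(bg) && length(bg) == 1L) bg <- d65_background(bg)
  bg <- .check_background(bg)
  dir <- .check_triplet(dir, "modulation direction")
  if (all(dir == 0)) stop("modulation direction must not be all zero")
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop("temporal frequency must be a single number >= 0")
  if (!is.numeric(area) || length(area) != 1L || area <= 0)
    stop("area must be a single number > 0")
  if (!is.numeric(ecc) || length(ecc) != 1L || ecc < 0)
    stop("eccentricity must be a single number >= 0")
  if (is.null(theta)) theta <- 0
  if (theta < 0 || theta >= 360)
    stop("visual-field angle must lie in [0, 360)")
  if (shape == "disc") {
    if (!is.null(rho) && !is.na(rho))
      warning("spatial frequency is ignored for disc stimuli")
    rho <- NA_real_
  } else {
    if (is.null(rho) || is.na(rho))
      stop("Gabor stimuli require a spatial frequency")
    if (rho < 0) stop("spatial frequency must be >= 0")
  }
  structure(list(bg = bg, dir = dir, rho = rho, omega = omega, area = area,
                 ecc = ecc, theta = theta, shape = shape),
            class = "csf_stimulus")
}

#' @export
print.csf_stimulus <- function(x, ...) {
  cat(sprintf(paste0("<csf_stimulus> %s: rho=%s cpd, omega=%g Hz, ",
                     "area=%g deg^2, ecc=%g deg (theta=%g), Y=%.4g cd/m^2\n"),
              x$shape, ifelse(is.na(x$rho), "-", format(x$rho)), x$omega,
              x$area, x$ecc, x$theta, x$bg[1] + x$bg[2]))
  invisible(x)
}

# Effective spatial frequency for Gabor evaluation: a nominal 0-cpd blob is
# a half-cycle Gabor; a hard floor keeps the log-frequency maths defined.
.effective_rho <- function(rho, area) {
  rho <- ifelse(rho <= 0, 0.5 / (2 * sqrt(area / pi)), rho)
  pmax(rho, .rho_min)
}
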