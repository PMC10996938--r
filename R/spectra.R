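#' Spectral radiance distributions
#'
#' A spectrum is a pair of equal-length vectors: a strictly increasing
#' wavelength grid (nm, within the visible range 360--830 nm) and a
#' nonnegative spectral radiance per wavelength. Radiance is in units such
#' that the luminous-efficiency-weighted integral gives luminance in cd/m^2.
#'
#' @param wavelengths_nm strictly increasing numeric vector, in \[360, 830\].
#' @param radiance nonnegative numeric vector, same length.
#' @return An object of class `csf_spectrum`.
#' @examples
#' sp <- csf_spectrum(seq(400, 700, 10), rep(1, 31))
#' cone_excitations(sp)
#' @export
csf_spectrum <- function(wavelengths_nm, radiance) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  radiance <- as.numeric(radiance)
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least two samples")
  if (length(wavelengths_nm) != length(radiance))
    stop("wavelength and radiance vectors must have the same length")
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(radiance)))
    stop("spectrum contains non-finite values")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (min(wavelengths_nm) < 360 || max(wavelengths_nm) > 830)
    stop("wavelengths must lie within [360, 830] nm")
  if (any(radiance < 0))
    stop("radiance must be nonnegative")
  structure(list(wavelengths_nm = wavelengths_nm, radiance = radiance),
            class = "csf_spectrum")
}

#' @export
print.csf_spectrum <- function(x, ...) {
  cat(sprintf("<csf_spectrum> %d samples, %.0f-%.0f nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm)))
  invisible(x)
}

# Package data caches (tables are small; loaded once per session).
.csf_cache <- new.env(parent = emptyenv())

#' Cone fundamental table shipped with the package
#'
#' Returns the packaged 2-degree cone-fundamental table: wavelength (nm) and
#' the L-, M- and S-cone spectral sensitivities normalised to unit peak, plus
#' the luminous efficiency curve `vbar = 0.689903*lbar + 0.348322*mbar`.
#'
#' The shipped table (`extdata/cone_fundamentals_synthetic.csv`) is a
#' constructed analytic stand-in (split log-Gaussian lobes peaking at 570,
#' 543 and 442 nm) with the qualitative shape of standard 2-degree
#' fundamentals; it is labelled synthetic in the filename. Users with access
#' to measured fundamentals can substitute any file with the same columns
#' via `options(chromaCSF.cone_fundamentals = "/path/to/file.csv")`.
#'
#' @return data.frame with columns `wavelength_nm`, `lbar`, `mbar`, `sbar`,
#'   `vbar`.
#' @export
cone_fundamentals <- function() {
  path <- getOption("chromaCSF.cone_fundamentals",
                    system.file("extdata", "cone_fundamentals_synthetic.csv",
                                package = "chromaCSF"))
  key <- paste0("cf:", path)
  if (!is.null(.csf_cache[[key]])) return(.csf_cache[[key]])
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "lbar", "mbar", "sbar", "vbar")
  if (!all(need %in% names(tab)))
    stop("cone fundamental table must have columns: ",
         paste(need, collapse = ", "))
  .csf_cache[[key]] <- tab
  tab
}

# Trapezoidal quadrature on an arbitrary increasing grid.
.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Linear interpolation of a fundamental column onto the spectrum grid;
# zero outside the tabulated range.
.interp_fund <- function(tab, col, wl) {
  stats::approx(tab$wavelength_nm, tab[[col]], xout = wl,
                yleft = 0, yright = 0)$y
}

#' Cone excitations from a spectral radiance distribution
#'
#' Integrates the spectrum against the 2-degree cone fundamentals using
#' trapezoidal quadrature on the spectrum's native grid (fundamentals are
#' linearly interpolated onto it):
#' `L = 0.689903 * integral(lbar * E)`, `M = 0.348322 * integral(mbar * E)`,
#' `S = 0.0371597 * integral(sbar * E)`. The scaling constants are chosen so
#' that L + M equals the luminous-efficiency-weighted integral of the
#' spectrum, i.e. luminance in cd/m^2.
#'
#' @param spectrum a [csf_spectrum()].
#' @return named numeric vector `c(L =, M =, S =)`.
#' @seealso [spectrum_luminance()], [d65_background()]
#' @export
cone_excitations <- function(spectrum) {
  if (!inherits(spectrum, "csf_spectrum"))
    spectrum <- csf_spectrum(spectrum$wavelengths_nm, spectrum$radiance)
  tab <- cone_fundamentals()
  wl <- spectrum$wavelengths_nm
  E <- spectrum$radiance
  c(L = 0.689903  * .trapz(wl, .interp_fund(tab, "lbar", wl) * E),
    M = 0.348322  * .trapz(wl, .interp_fund(tab, "mbar", wl) * E),
    S = 0.0371597 * .trapz(wl, .interp_fund(tab, "sbar", wl) * E))
}

#' Luminance of a spectrum via the luminous efficiency function
#'
#' Integrates the spectrum against the luminous efficiency curve
#' (`vbar` column of [cone_fundamentals()]); by the choice of cone scaling
#' constants this equals `L + M` from [cone_excitations()] up to quadrature
#' error, and is used as an independent check of that identity.
#'
#' @inheritParams cone_excitations
#' @return luminance in cd/m^2.
#' @export
spectrum_luminance <- function(spectrum) {
  if (!inherits(spectrum, "csf_spectrum"))
    spectrum <- csf_spectrum(spectrum$wavelengths_nm, spectrum$radiance)
  tab <- cone_fundamentals()
  wl <- spectrum$wavelengths_nm
  .trapz(wl, .interp_fund(tab, "vbar", wl) * spectrum$radiance)
}

#' D65-like grey background at a given luminance
#'
#' Cone excitations of the packaged daylight-white spectrum
#' (`extdata/d65_spectrum_synthetic.csv`, a 6504 K Planckian radiator used
#' as a constructed stand-in for the D65 illuminant and labelled synthetic),
#' scaled so that `L + M` equals the requested luminance. The chromaticity
#' (ratios between L, M and S) is independent of luminance.
#'
#' @param luminance background luminance in cd/m^2, > 0.
#' @return named numeric vector `c(L =, M =, S =)` with `L + M == luminance`.
#' @examples
#' d65_background(100)
#' @export
d65_background <- function(luminance) {
  if (!is.numeric(luminance) || length(luminance) != 1L ||
      !is.finite(luminance) || luminance <= 0)
    stop("luminance must be a single positive number")
  base <- .csf_cache[["d65_unit"]]
  if (is.null(base)) {
    path <- system.file("extdata", "d65_spectrum_synthetic.csv",
                        package = "chromaCSF")
    tab <- utils::read.csv(path)
    lms <- cone_excitations(csf_spectrum(tab$wavelength_nm, tab$radiance))
    base <- lms / (lms[["L"]] + lms[["M"]])  # unit-luminance excitations
    .csf_cache[["d65_unit"]] <- base
  }
  base * luminance
}

#' Read a two-column spectrum file
#'
#' Reads a delimited text file with columns `wavelength_nm` and `radiance`
#' (header required) into a [csf_spectrum()].
#'
#' @param path file path.
#' @return a `csf_spectrum`.
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "radiance") %in% names(tab)))
    stop("spectrum file must have columns wavelength_nm, radiance: ", path)
  csf_spectrum(tab$wavelength_nm, tab$radiance)
}
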