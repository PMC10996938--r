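# Regenerates the packaged text tables under inst/extdata/.
# Run from the repository root: Rscript tools/make_extdata.R
#
# The cone-fundamental and illuminant tables are constructed analytic
# stand-ins (hence the _synthetic suffix): split log-Gaussian cone
# sensitivity lobes with realistic peak wavelengths, and a 6504 K Planckian
# radiator as the daylight-white spectrum.

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

split_log_gauss <- function(wl, peak, w_short, w_long) {
  w <- ifelse(wl < peak, w_short, w_long)
  exp(-0.5 * (log(wl / peak) / w)^2)
}

wl <- 390:830
lbar <- split_log_gauss(wl, 570, 0.085, 0.050)
mbar <- split_log_gauss(wl, 543, 0.080, 0.045)
sbar <- split_log_gauss(wl, 442, 0.075, 0.042)
vbar <- 0.689903 * lbar + 0.348322 * mbar

cf <- data.frame(wavelength_nm = wl,
                 lbar = signif(lbar, 7), mbar = signif(mbar, 7),
                 sbar = signif(sbar, 7), vbar = signif(vbar, 7))
write.csv(cf, "inst/extdata/cone_fundamentals_synthetic.csv",
          row.names = FALSE, quote = FALSE)

# Planckian radiator at 6504 K, normalised to 1 at 560 nm.
planck <- function(wl_nm, temp) {
  l <- wl_nm * 1e-9
  h <- 6.62607015e-34; c <- 299792458; kB <- 1.380649e-23
  (2 * h * c^2 / l^5) / (exp(h * c / (l * kB * temp)) - 1)
}
wl5 <- seq(390, 830, by = 5)
rad <- planck(wl5, 6504) / planck(560, 6504)
d65 <- data.frame(wavelength_nm = wl5, radiance = signif(rad, 7))
write.csv(d65, "inst/extdata/d65_spectrum_synthetic.csv",
          row.names = FALSE, quote = FALSE)

# Default parameter file (requires the package to be loadable).
if (requireNamespace("pkgload", quietly = TRUE)) {
  pkgload::load_all(".", quiet = TRUE)
} else {
  library(chromaCSF)
}
write_params(default_params(), "inst/extdata/default_params.txt")
cat("extdata regenerated\n")
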