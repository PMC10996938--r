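# Component response functions: temporal channels, spatial envelopes,
# summation, luminance gain, eccentricity.

p <- default_params()

test_that("sustained response is 1 at 0 Hz, has the closed form, and is low-pass", {
  expect_identical(sustained_response(0, p$ach$sustained), 1)
  expect_equal(sustained_response(1, list(beta = 1, sigma = 1)), exp(-1))
  w <- 10^seq(-1, 2, length.out = 60)
  for (ch in list(p$ach$sustained, p$rg$sustained, p$yv$sustained))
    expect_true(all(diff(sustained_response(w, ch)) < 0))
})

test_that("transient peak frequency is linear in log luminance with a floor", {
  ch <- p$ach$transient
  expect_equal(transient_peak(1, ch), ch$c_omega)
  expect_equal(transient_peak(100, list(m_omega = 0, c_omega = 4)), 4)
  expect_gt(transient_peak(100, ch), transient_peak(1, ch))
  # far below the fitted range the line would go negative; the floor holds
  expect_equal(transient_peak(1e-12, list(m_omega = 3, c_omega = 0)), 0.1)
})

test_that("transient response peaks at the luminance-dependent peak and shifts right", {
  ch <- p$ach$transient
  for (Y in c(0.1, 10, 1000))
    expect_equal(transient_response(transient_peak(Y, ch), Y, ch), 1)
  expect_equal(transient_response(0, 1, list(beta = 1, sigma = 1,
                                             m_omega = 0, c_omega = 5)),
               exp(-25))
  # grid-argmax oracle: the peak location is nondecreasing in luminance
  w <- seq(0.1, 60, by = 0.05)
  amax <- sapply(c(0.02, 0.2, 2, 20, 200, 2000),
                 function(Y) w[which.max(transient_response(w, Y, ch))])
  expect_true(all(diff(amax) >= 0))
  expect_gt(amax[6], amax[1])
})

test_that("log-parabola peaks at rho_m, is log-symmetric, with both bandwidth readings", {
  expect_equal(log_parabola(3, 3, 0.77), 1)
  for (x in c(1.3, 2, 7))
    expect_equal(log_parabola(3 * x, 3, 1.1), log_parabola(3 / x, 3, 1.1))
  expect_equal(log_parabola(10, 1, 1), 10^(-1 / 2))
  # alternative bandwidth parameterisation: denominator 2 * k_b^2
  expect_equal(log_parabola(10, 1, 1, bandwidth_mode = "sq"), 10^(-1 / 2))
  expect_equal(log_parabola(10, 1, 2, bandwidth_mode = "sq"), 10^(-1 / 8))
  expect_error(log_parabola(0, 1, 1), "> 0")
})

test_that("achromatic envelope truncates to a plateau below the peak", {
  rho_m <- 4; k_b <- 1; k_a <- 0.7
  # high-frequency side is the bare parabola
  for (r in c(4, 6, 30))
    expect_equal(spatial_envelope_achromatic(r, rho_m, k_b, k_a),
                 log_parabola(r, rho_m, k_b))
  # deep low-frequency limit is the plateau
  expect_equal(spatial_envelope_achromatic(1e-4, rho_m, k_b, k_a), 1 - k_a)
  # at the crossover (solved in closed form) the branches agree
  rho_star <- rho_m * 10^(-sqrt(-2^k_b * log10(1 - k_a)))
  expect_lt(rho_star, rho_m)
  expect_equal(spatial_envelope_achromatic(rho_star * (1 - 1e-9), rho_m,
                                           k_b, k_a),
               spatial_envelope_achromatic(rho_star * (1 + 1e-9), rho_m,
                                           k_b, k_a),
               tolerance = 1e-6)
})

test_that("chromatic envelope is flat below the peak, continuous, then decreasing", {
  rho_m <- 0.5; k_b <- 1.2
  expect_identical(spatial_envelope_chromatic(rho_m / 2, rho_m, k_b), 1)
  expect_equal(spatial_envelope_chromatic(rho_m * (1 + 1e-12), rho_m, k_b),
               1, tolerance = 1e-9)
  r <- 2^seq(-1, 5, length.out = 40)
  v <- spatial_envelope_chromatic(r, rho_m, k_b)
  expect_true(all(diff(v[r > rho_m]) < 0))
})

test_that("critical area starts at a0, halves at rho0, and shrinks with frequency", {
  ch <- list(a0 = 2.5, rho0 = 0.5)
  expect_equal(critical_area(0, ch), 2.5)
  expect_equal(critical_area(0.5, ch), 1.25)
  expect_lt(critical_area(1e4, ch), 1e-6)
  r <- 2^seq(-4, 6, length.out = 50)
  expect_true(all(diff(critical_area(r, ch)) < 0))
})

test_that("area factor saturates at the critical number of cycles", {
  ch <- list(a0 = 2.5, rho0 = 0.5)
  rho <- 2
  ax <- critical_area(rho, ch)
  expect_equal(area_sensitivity(rho, 1e12, ch), rho * sqrt(ax),
               tolerance = 1e-9)
  expect_equal(area_sensitivity(rho, ax, ch), rho * sqrt(ax / 2))
  expect_equal(area_sensitivity(2 * rho, 1, list(a0 = 2.5, rho0 = 1e9)),
               2 * area_sensitivity(rho, 1, list(a0 = 2.5, rho0 = 1e9)))
  a <- 10^seq(-2, 2, length.out = 30)
  expect_true(all(diff(area_sensitivity(1, a, ch)) > 0))
})

test_that("achromatic sustained gain rises, plateaus, and declines (unimodal)", {
  ch <- p$ach$sustained
  Y <- 10^seq(-3, log10(20000), length.out = 200)
  g <- luminance_gain_ach_sustained(Y, ch)
  expect_lt(luminance_gain_ach_sustained(1e-9, ch), 1e-4 * max(g))
  expect_lt(luminance_gain_ach_sustained(1e12, ch), 1e-2 * max(g))
  # grid-scan oracle for unimodality: one sign change of the differences
  s <- sign(diff(g))
  expect_equal(sum(diff(s[s != 0]) != 0), 1)
})

test_that("chromatic gain increases to its asymptote", {
  ch <- p$rg$sustained
  expect_equal(luminance_gain_chromatic(1e12, ch), ch$ks1, tolerance = 1e-9)
  expect_equal(luminance_gain_chromatic(5, list(ks1 = 7, ks2 = 0, ks3 = 2)), 7)
  Y <- 10^seq(-3, 4, length.out = 40)
  expect_true(all(diff(luminance_gain_chromatic(Y, ch)) > 0))
})

test_that("transient gain is a power law of luminance", {
  expect_equal(luminance_gain_transient(1, list(ks1 = 0.4, ks2 = 9)), 9)
  expect_equal(luminance_gain_transient(100, list(ks1 = 0.5, ks2 = 1)), 10)
  Y <- 10^seq(-2, 4, length.out = 20)
  lg <- log10(luminance_gain_transient(Y, p$ach$transient))
  slopes <- diff(lg) / diff(log10(Y))
  expect_equal(slopes, rep(p$ach$transient$ks1, length(slopes)))
})

test_that("peak frequency shifts with luminance only for the achromatic sustained channel", {
  expect_equal(peak_frequency(1e12, p$ach$sustained), p$ach$sustained$k_rho1,
               tolerance = 1e-9)
  expect_gt(peak_frequency(200, p$ach$sustained),
            peak_frequency(0.2, p$ach$sustained))
  for (ch in list(p$ach$transient, p$rg$sustained, p$yv$sustained))
    expect_equal(peak_frequency(0.01, ch), peak_frequency(10000, ch))
})

test_that("eccentricity weights blend nasal and non-nasal coefficients", {
  ep <- list(ke1 = 0.02, ke2 = 0.04, ke1_nasal = 0.01, ke2_nasal = 0.02)
  w <- eccentricity_weights(180, ep)
  expect_equal(c(w$ke1, w$ke2), c(0.01, 0.02))
  w <- eccentricity_weights(0, ep)
  expect_equal(c(w$ke1, w$ke2), c(0.02, 0.04))
  w <- eccentricity_weights(135, ep)
  expect_equal(c(w$ke1, w$ke2), c(0.015, 0.03))
  # anywhere at least 90 deg from the nasal meridian: non-nasal exactly
  w <- eccentricity_weights(45, ep)
  expect_equal(c(w$ke1, w$ke2), c(0.02, 0.04))
})

test_that("eccentricity attenuation is 1 in the fovea and log-linear outside", {
  ep <- list(ke1 = 0, ke2 = 0.1, ke1_nasal = 0, ke2_nasal = 0.1)
  expect_equal(eccentricity_attenuation(0, 5, 0, p$ach$ecc), 1)
  expect_equal(eccentricity_attenuation(10, 3, 0, ep), 0.1)
  e <- seq(0, 40, 5)
  le <- log10(eccentricity_attenuation(e, 2, 90, p$yv$ecc))
  slopes <- diff(le) / diff(e)
  expect_equal(slopes, rep(slopes[1], length(slopes)))
  # steeper decline at higher spatial frequency when ke1 > 0
  expect_lt(eccentricity_attenuation(20, 8, 0, p$ach$ecc),
            eccentricity_attenuation(20, 1, 0, p$ach$ecc))
})
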