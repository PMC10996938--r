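# Shared fixtures: randomized stimulus specs, a bisection oracle for the
# detection threshold, and small hand-built measurement tables.

# Draw a random but valid stimulus spec. Backgrounds are either D65-like
# grey or a random chromatic background; directions are arbitrary nonzero
# cone increments at arbitrary magnitude.
random_spec <- function(shape = c("gabor", "disc")) {
  shape <- match.arg(shape)
  Y <- 10^runif(1, -1.5, 3.5)
  bg <- if (runif(1) < 0.5) {
    d65_background(Y)
  } else {
    b <- c(runif(1, 0.4, 0.8), 0, 0)
    b[2] <- 1 - b[1]
    c(b[1] * Y, b[2] * Y, runif(1, 0.001, 0.05) * Y)
  }
  dir <- rnorm(3) * 10^runif(1, -3, 3)
  while (all(dir == 0)) dir <- rnorm(3)
  ecc <- if (runif(1) < 0.3) runif(1, 0, 40) else 0
  csf_stimulus(bg = bg, dir = dir,
               rho = if (shape == "gabor") 2^runif(1, -3, 5) else NULL,
               omega = if (runif(1) < 0.3) 0 else 2^runif(1, -1, 5),
               area = 10^runif(1, -2, 1.7),
               ecc = ecc, theta = runif(1, 0, 360 - 1e-9),
               shape = shape)
}

# Independent threshold oracle: bisect on the scale of the modulation
# direction until the contrast energy is 1, then report the inverse cone
# contrast of the scaled increment. Makes no use of the energy's
# homogeneity, so it cross-checks the analytic inversion.
oracle_sensitivity <- function(spec, params, tol = 1e-13) {
  energy_at <- function(s) {
    sp <- spec
    sp$dir <- spec$dir * s
    contrast_energy(sp, params)
  }
  # bracket the unit-energy crossing by decade steps (energy is monotone
  # increasing in the scale), then bisect in log scale
  hi <- 1
  for (i in 1:40) {
    if (energy_at(hi) >= 1) break
    hi <- hi * 10
  }
  lo <- hi
  for (i in 1:40) {
    if (energy_at(lo) <= 1) break
    lo <- lo / 10
  }
  if (energy_at(lo) > 1 || energy_at(hi) < 1) stop("oracle bracket failed")
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (energy_at(mid) < 1) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  s <- sqrt(lo * hi)
  1 / cone_contrast(spec$dir * s, spec$bg)
}

# Minimal valid measurement table built in code.
tiny_records <- function(n = 6, dataset_id = "toy", Y = 30) {
  bg <- d65_background(Y)
  data.frame(dataset_id = dataset_id,
             L0 = bg[[1]], M0 = bg[[2]], S0 = bg[[3]],
             dL = bg[[1]], dM = bg[[2]], dS = 0,
             rho_cpd = 2^seq(-1, 4, length.out = n),
             omega_hz = 0, area_deg2 = pi, ecc_deg = 0, theta_deg = 0,
             shape = "gabor",
             sensitivity = 100)
}
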