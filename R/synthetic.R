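# Synthetic measurement generator: produces tables with the statistical
# structure of consolidated threshold data -- sparse, non-overlapping
# stimulus grids per dataset family, per-dataset multiplicative sensitivity
# shifts, and log-domain Gaussian measurement noise.

# Run code with a locally seeded RNG, restoring global RNG state after.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.cardinal_dirs <- function(bg) {
  list(ach = c(bg[1], bg[2], 0),   # background-proportional luminance
       rg = c(1, -1, 0),
       yv = c(0, 0, 1))
}

# One stimulus-grid data.frame per template family. Grids are deliberately
# sparse and non-overlapping across families, mimicking consolidated data
# where each study measures a different slice of the stimulus space.
.template_grid <- function(template) {
  grid <- switch(
    template,
    # HDR-like reference set: wide luminance range, static fixed-cycle
    # (~2 visible cycles) Gabors in all three cardinal directions (its
    # real-world counterpart measured achromatic and chromatic portions on
    # the same apparatus; keeping them in one dataset anchors every
    # mechanism's gain at the reference shift), plus a fixed-size
    # achromatic subset.
    "achromatic-hdr" = {
      g <- expand.grid(rho_cpd = c(0.5, 1, 2, 4, 6, 12, 24),
                       Y = c(0.02, 2, 20, 200, 2000, 10000),
                       dir = c("ach", "rg", "yv"),
                       stringsAsFactors = FALSE)
      g$area_deg2 <- pi / g$rho_cpd^2
      g2 <- expand.grid(rho_cpd = c(0.5, 1, 2, 4, 6, 12, 24),
                        Y = c(0.02, 2, 20, 200, 2000, 10000),
                        dir = "ach", stringsAsFactors = FALSE)
      g2$area_deg2 <- 12.5
      g <- rbind(g, g2)
      g$omega_hz <- 0; g$ecc_deg <- 0; g$theta_deg <- 0
      g$shape <- "gabor"
      g
    },
    # low-frequency chromatic set: red-green and yellow-violet modulations
    # at moderate luminances and a small fixed size.
    "chromatic-lowfreq" = {
      g <- expand.grid(rho_cpd = c(0.125, 0.25, 0.5, 1, 2, 4),
                       Y = c(0.02, 0.2, 2, 20, 200),
                       dir = c("rg", "yv"),
                       area_deg2 = 0.78,
                       stringsAsFactors = FALSE)
      g$omega_hz <- 0; g$ecc_deg <- 0; g$theta_deg <- 0
      g$shape <- "gabor"
      g
    },
    # peripheral discs: all three cardinal directions, no spatial frequency.
    "peripheral-disc" = {
      g <- expand.grid(ecc_deg = c(10, 20, 30, 40, 50),
                       area_deg2 = c(0.2, 3.14, 50.27),
                       dir = c("ach", "rg", "yv"),
                       stringsAsFactors = FALSE)
      g$rho_cpd <- NA_real_; g$Y <- 100
      g$omega_hz <- 0; g$theta_deg <- 0
      g$shape <- "disc"
      g
    },
    # joint spatial x temporal frequency sampling at three luminances.
    "spatiotemporal" = {
      g <- expand.grid(rho_cpd = c(0.5, 1, 2, 4, 10, 20),
                       omega_hz = c(0.5, 2, 8, 16, 32),
                       Y = c(0.3, 20, 870),
                       stringsAsFactors = FALSE)
      g$area_deg2 <- 1; g$ecc_deg <- 0; g$theta_deg <- 0
      g$shape <- "gabor"; g$dir <- "ach"
      g
    },
    stop("unknown template: ", template)
  )
  grid
}

.template_names <- c("achromatic-hdr", "chromatic-lowfreq",
                     "peripheral-disc", "spatiotemporal")

#' Design a synthetic dataset family
#'
#' Returns a ready-made synthetic design for one of four dataset families
#' that together touch every model dimension: `"achromatic-hdr"` (static
#' achromatic Gabors over 0.5--24 cpd and 0.02--10,000 cd/m^2),
#' `"chromatic-lowfreq"` (red-green and yellow-violet Gabors at low spatial
#' frequencies), `"peripheral-disc"` (disc stimuli at 10--50 deg
#' eccentricity, all three cardinal directions), and `"spatiotemporal"`
#' (joint spatial x temporal frequency grid). Backgrounds are D65-like grey
#' at the stated luminance and modulation directions are cardinal.
#'
#' @param template family name (see above).
#' @param noise_db log-domain Gaussian measurement noise, dB standard
#'   deviation (default 3 dB, a typical interobserver spread).
#' @param shift true multiplicative sensitivity shift of the dataset.
#' @return list describing the dataset family (id, grid, noise, shift).
#' @export
make_dataset_like <- function(template = .template_names, noise_db = 3,
                              shift = 1) {
  template <- match.arg(template)
  list(dataset_id = template, grid = .template_grid(template),
       noise_db = noise_db, shift = shift)
}

#' Assemble a synthetic design
#'
#' @param templates character vector of family names, or a list of family
#'   descriptions from [make_dataset_like()].
#' @param true_params the generating (truth) parameter set; default
#'   [default_params()].
#' @param true_shifts named numeric vector of per-dataset multiplicative
#'   shifts (default 1 for every dataset; the first dataset is the
#'   reference and must have shift 1).
#' @param noise_db per-dataset noise, recycled; dB standard deviation.
#' @param seed integer RNG seed.
#' @return object of class `csf_design`.
#' @export
synthetic_design <- function(templates = .template_names,
                             true_params = default_params(),
                             true_shifts = NULL, noise_db = 3,
                             seed = 1L) {
  if (is.character(templates)) {
    noise_db <- rep_len(noise_db, length(templates))
    fams <- Map(make_dataset_like, templates, noise_db)
  } else {
    fams <- templates
  }
  ids <- vapply(fams, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids in design")
  if (!is.null(true_shifts)) {
    for (id in names(true_shifts)) {
      i <- match(id, ids)
      if (is.na(i)) stop("shift given for unknown dataset: ", id)
      fams[[i]]$shift <- true_shifts[[id]]
    }
  }
  for (f in fams) {
    if (f$noise_db < 0) stop("noise_db must be >= 0")
    if (f$shift <= 0) stop("shifts must be > 0")
    if (nrow(f$grid) == 0L) stop("empty stimulus grid")
  }
  structure(list(datasets = fams, true_params = csf_params(true_params),
                 seed = as.integer(seed)),
            class = "csf_design")
}

#' Generate a synthetic measurement table
#'
#' For every grid point the emitted sensitivity is
#' `shift_d * model(true_params) * 10^(eps / 20)` with
#' `eps ~ Normal(0, noise_db)`. Rows whose noisy sensitivity falls below 1
#' are emitted anyway, so the downstream filter is exercised. The returned
#' truth table keeps the noiseless values.
#'
#' @param design a [synthetic_design()].
#' @return list with `records` (measurement schema), `metas` (dataset
#'   metadata; the first dataset is flagged as the reference), and `truth`
#'   (records plus noiseless `sensitivity_true` and the unshifted
#'   `model_sensitivity`).
#' @examples
#' d <- synthetic_design("spatiotemporal", noise_db = 0, seed = 7)
#' g <- generate_measurements(d)
#' head(g$records)
#' @export
generate_measurements <- function(design) {
  stopifnot(inherits(design, "csf_design"))
  recs <- lapply(design$datasets, function(f) {
    g <- f$grid
    bg <- vapply(g$Y, function(y) d65_background(y), numeric(3))
    dirs <- vapply(seq_len(nrow(g)), function(i) {
      .cardinal_dirs(bg[, i])[[g$dir[i]]]
    }, numeric(3))
    data.frame(dataset_id = f$dataset_id,
               L0 = bg[1, ], M0 = bg[2, ], S0 = bg[3, ],
               dL = dirs[1, ], dM = dirs[2, ], dS = dirs[3, ],
               rho_cpd = g$rho_cpd, omega_hz = g$omega_hz,
               area_deg2 = g$area_deg2, ecc_deg = g$ecc_deg,
               theta_deg = g$theta_deg, shape = g$shape,
               sensitivity = NA_real_)
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  pred <- csf_predict(records, design$true_params)
  shift <- rep(vapply(design$datasets, `[[`, numeric(1), "shift"),
               vapply(recs, nrow, integer(1)))
  noise_db <- rep(vapply(design$datasets, `[[`, numeric(1), "noise_db"),
                  vapply(recs, nrow, integer(1)))
  eps <- .with_seed(design$seed, stats::rnorm(nrow(records)))
  records$sensitivity <- shift * pred * 10^(eps * noise_db / 20)
  truth <- records
  truth$sensitivity_true <- shift * pred
  truth$model_sensitivity <- pred
  metas <- data.frame(
    dataset_id = vapply(design$datasets, `[[`, character(1), "dataset_id"),
    n_observers = 1L,
    source = "synthetic",
    is_reference = seq_along(design$datasets) == 1L)
  list(records = records, metas = metas, truth = truth)
}
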