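# Model parameter set: construction, validation, flat-key serialization.

# Required numeric keys, in canonical order. Keys are <mechanism>.<channel>.<param>.
.param_keys <- c(
  # achromatic sustained channel
  "ach.sustained.beta", "ach.sustained.sigma",
  "ach.sustained.k_rho1", "ach.sustained.k_rho2", "ach.sustained.k_rho3",
  "ach.sustained.k_b", "ach.sustained.k_a",
  "ach.sustained.a0", "ach.sustained.rho0",
  "ach.sustained.ks1", "ach.sustained.ks2", "ach.sustained.ks3",
  "ach.sustained.ks4", "ach.sustained.ks5",
  # achromatic transient channel
  "ach.transient.beta", "ach.transient.sigma",
  "ach.transient.m_omega", "ach.transient.c_omega",
  "ach.transient.k_rho", "ach.transient.k_b", "ach.transient.k_a",
  "ach.transient.a0", "ach.transient.rho0",
  "ach.transient.ks1", "ach.transient.ks2",
  # achromatic eccentricity (shared by both temporal channels)
  "ach.ecc.ke1", "ach.ecc.ke2", "ach.ecc.ke1_nasal", "ach.ecc.ke2_nasal",
  # red-green sustained
  "rg.sustained.beta", "rg.sustained.sigma",
  "rg.sustained.k_rho", "rg.sustained.k_b",
  "rg.sustained.a0", "rg.sustained.rho0",
  "rg.sustained.ks1", "rg.sustained.ks2", "rg.sustained.ks3",
  "rg.ecc.ke1", "rg.ecc.ke2", "rg.ecc.ke1_nasal", "rg.ecc.ke2_nasal",
  # yellow-violet sustained
  "yv.sustained.beta", "yv.sustained.sigma",
  "yv.sustained.k_rho", "yv.sustained.k_b",
  "yv.sustained.a0", "yv.sustained.rho0",
  "yv.sustained.ks1", "yv.sustained.ks2", "yv.sustained.ks3",
  "yv.ecc.ke1", "yv.ecc.ke2", "yv.ecc.ke1_nasal", "yv.ecc.ke2_nasal",
  # disc extension (fixed constants, never fitted)
  "disc.beta", "disc.a_disc"
)

# Keys that may take any sign (the transient-peak line can have negative
# slope or intercept); eccentricity coefficients must be >= 0; k_a in (0,1);
# everything else must be > 0.
.param_free_sign <- c("ach.transient.m_omega", "ach.transient.c_omega")
.param_nonneg <- grep("\\.ecc\\.", .param_keys, value = TRUE)
.param_unit_interval <- c("ach.sustained.k_a", "ach.transient.k_a")

.flatten_params <- function(p) {
  out <- vapply(.param_keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    v <- p[[parts[1]]][[parts[2]]]
    if (length(parts) == 3L) v <- v[[parts[3]]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  names(out) <- .param_keys
  out
}

.unflatten_params <- function(flat) {
  p <- list()
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(parts) == 3L) {
      p[[parts[1]]][[parts[2]]][[parts[3]]] <- flat[[k]]
    } else {
      p[[parts[1]]][[parts[2]]] <- flat[[k]]
    }
  }
  p
}

#' Construct and validate a model parameter set
#'
#' A parameter set is a nested list keyed by mechanism (`ach`, `rg`, `yv`,
#' `disc`) and channel (`sustained`, `transient`, `ecc`), holding all
#' temporal, spatial, area, luminance and eccentricity parameters of the
#' model plus the fixed disc-extension constants, and an `options` entry
#' with `bandwidth_mode` (`"pow2"`: log-parabola denominator `2^k_b`;
#' `"sq"`: `2*k_b^2`). Every numeric key must be present; missing keys are a
#' hard error, with no silent defaults.
#'
#' @param x nested list (as from [default_params()] or [read_params()]).
#' @return validated object of class `csf_params`.
#' @export
csf_params <- function(x) {
  if (inherits(x, "csf_params")) x <- unclass(x)
  flat <- .flatten_params(x)
  missing <- names(flat)[is.na(flat)]
  if (length(missing))
    stop("missing model parameter(s): ", paste(missing, collapse = ", "))
  pos <- setdiff(.param_keys,
                 c(.param_free_sign, .param_nonneg, .param_unit_interval))
  bad <- pos[flat[pos] <= 0]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  badn <- .param_nonneg[flat[.param_nonneg] < 0]
  if (length(badn))
    stop("eccentricity parameter(s) must be >= 0: ",
         paste(badn, collapse = ", "))
  badu <- .param_unit_interval[flat[.param_unit_interval] <= 0 |
                                 flat[.param_unit_interval] >= 1]
  if (length(badu))
    stop("truncation depth k_a must lie in (0, 1): ",
         paste(badu, collapse = ", "))
  p <- .unflatten_params(flat)
  opts <- x$options
  if (is.null(opts)) opts <- list()
  if (is.null(opts$bandwidth_mode)) opts$bandwidth_mode <- "pow2"
  if (!opts$bandwidth_mode %in% c("pow2", "sq"))
    stop("options.bandwidth_mode must be 'pow2' or 'sq'")
  p$options <- opts
  structure(p, class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  flat <- .flatten_params(x)
  cat(sprintf("<csf_params> %d parameters (bandwidth_mode = %s)\n",
              length(flat), x$options$bandwidth_mode))
  cat(sprintf("  ach sustained peak (high-Y): %.3g cpd, transient peak: %.3g cpd\n",
              x$ach$sustained$k_rho1, x$ach$transient$k_rho))
  cat(sprintf("  chromatic peaks: rg %.3g cpd, yv %.3g cpd\n",
              x$rg$sustained$k_rho, x$yv$sustained$k_rho))
  invisible(x)
}

#' Default model parameter set
#'
#' A hand-set, plausible parameter set shipped with the package. It is not a
#' fit to published data; values were chosen once so that the model exhibits
#' the qualitative behaviour expected of human contrast sensitivity:
#' band-pass static achromatic and low-pass chromatic spatial tuning,
#' sustained low-pass and transient band-pass temporal channels with a
#' luminance-dependent transient peak, DeVries-Rose rise / Weber plateau /
#' high-luminance decline of achromatic gain, and faster peripheral decline
#' at high spatial frequencies. It serves as the truth set for synthetic
#' data generation and as the default optimisation start.
#'
#' @return a [csf_params()] object.
#' @export
default_params <- function() {
  csf_params(list(
    ach = list(
      sustained = list(beta = 1.3, sigma = 100,
                       k_rho1 = 4, k_rho2 = 1.5, k_rho3 = 0.4,
                       k_b = 0.8, k_a = 0.7,
                       a0 = 2.5, rho0 = 0.5,
                       ks1 = 300, ks2 = 30, ks3 = 0.8, ks4 = 7000, ks5 = 1),
      transient = list(beta = 1.5, sigma = 150,
                       m_omega = 2.5, c_omega = 5,
                       k_rho = 0.1, k_b = 1.2, k_a = 0.5,
                       a0 = 10, rho0 = 2,
                       ks1 = 0.35, ks2 = 15),
      ecc = list(ke1 = 0.02, ke2 = 0.02,
                 ke1_nasal = 0.015, ke2_nasal = 0.01)
    ),
    rg = list(
      sustained = list(beta = 1.2, sigma = 30,
                       k_rho = 0.5, k_b = 1.2,
                       a0 = 40, rho0 = 0.1,
                       ks1 = 2000, ks2 = 30, ks3 = 0.7),
      ecc = list(ke1 = 0.01, ke2 = 0.035,
                 ke1_nasal = 0.008, ke2_nasal = 0.03)
    ),
    yv = list(
      sustained = list(beta = 1.2, sigma = 20,
                       k_rho = 0.4, k_b = 1.2,
                       a0 = 60, rho0 = 0.08,
                       ks1 = 150, ks2 = 30, ks3 = 0.7),
      ecc = list(ke1 = 0.015, ke2 = 0.02,
                 ke1_nasal = 0.012, ke2_nasal = 0.015)
    ),
    disc = list(beta = 3.01142, a_disc = 2.42437),
    options = list(bandwidth_mode = "pow2")
  ))
}

#' Write / read a parameter file
#'
#' Flat key-value text format, one `key value` pair per line, keys named
#' `<mechanism>.<channel>.<param>` (e.g. `ach.sustained.k_b`). Numeric
#' values are written with 17 significant digits so that a write/read
#' round-trip is bit-exact. Lines starting with `#` are comments. String
#' options are written as `options.<name> <value>`. A missing numeric key on
#' read is a hard error.
#'
#' @param params a [csf_params()] object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `csf_params` object.
#' @export
write_params <- function(params, path) {
  params <- csf_params(params)
  flat <- .flatten_params(params)
  lines <- c("# chromaCSF model parameter file",
             sprintf("%s %.17g", names(flat), flat),
             sprintf("options.bandwidth_mode %s",
                     params$options$bandwidth_mode))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(parts, `[`, character(1), 1L)
  vals <- vapply(parts, `[`, character(1), 2L)
  if (anyDuplicated(keys))
    stop("duplicate key(s) in parameter file: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  flat <- as.list(suppressWarnings(as.numeric(vals)))
  names(flat) <- keys
  num <- flat[names(flat) %in% .param_keys]
  bad <- names(num)[vapply(num, function(v) is.na(v), logical(1))]
  if (length(bad))
    stop("non-numeric value for parameter(s): ", paste(bad, collapse = ", "))
  p <- .unflatten_params(num)
  if ("options.bandwidth_mode" %in% keys)
    p$options <- list(bandwidth_mode = vals[keys == "options.bandwidth_mode"])
  csf_params(p)  # errors on any missing key
}

#' Flatten a parameter set to a named numeric vector
#'
#' Canonical ordering, used by the optimiser and by serialization.
#'
#' @param params a [csf_params()] object.
#' @return named numeric vector over all numeric parameter keys.
#' @export
params_to_vector <- function(params) {
  .flatten_params(csf_params(params))
}

#' @rdname params_to_vector
#' @param flat named numeric vector as returned by `params_to_vector`.
#' @param template a `csf_params` providing options for the rebuilt object.
#' @export
vector_to_params <- function(flat, template = default_params()) {
  p <- .unflatten_params(as.list(flat))
  p$options <- csf_params(template)$options
  csf_params(p)
}
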