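# Measurement-table I/O: the flat delimited schema for consolidated
# threshold data, aperture standardisation, and the sensitivity filter.

# Required columns of the measurement schema, in canonical order. The
# encoding is cone-native (background and direction in cone excitations) so
# no opponent-space convention is baked into the files. Sensitivities are
# per-condition means over observers.
.schema_cols <- c("dataset_id", "L0", "M0", "S0", "dL", "dM", "dS",
                  "rho_cpd", "omega_hz", "area_deg2", "ecc_deg",
                  "theta_deg", "shape", "sensitivity")
.schema_numeric <- setdiff(.schema_cols, c("dataset_id", "shape"))

.check_schema <- function(records) {
  missing <- setdiff(.schema_cols, names(records))
  if (length(missing))
    stop("measurement table is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(records)
}

#' Standardise an aperture description to an equivalent area
#'
#' Non-Gaussian apertures are mapped to the equivalent Gabor area
#' `pi * sigma^2`: a circular aperture of diameter `d` is treated as a
#' Gaussian envelope with `sigma = d / 2` (area `pi * (d/2)^2`); a
#' rectangular aperture of area `a` is treated as a disc aperture of the
#' same area (`pi * sigma^2 = a`); a Gaussian envelope of width `sigma`
#' has area `pi * sigma^2`.
#'
#' @param type `"circular"`, `"rectangular"` or `"gaussian"`.
#' @param value the aperture dimension: diameter in degrees (circular),
#'   area in deg^2 (rectangular), or sigma in degrees (gaussian). Must be
#'   positive.
#' @return equivalent area in deg^2.
#' @examples
#' standardize_aperture("circular", 2)      # pi
#' standardize_aperture("rectangular", 4)   # 4
#' standardize_aperture("gaussian", 0.5)    # pi / 4
#' @export
standardize_aperture <- function(type = c("circular", "rectangular",
                                          "gaussian"), value) {
  type <- match.arg(type)
  if (!is.numeric(value) || any(value <= 0))
    stop("aperture dimension must be positive")
  switch(type,
         circular = pi * (value / 2)^2,
         rectangular = value,
         gaussian = pi * value^2)
}

#' Drop measurements with sensitivity below one
#'
#' Sensitivities below 1 correspond to contrast thresholds above 1, which
#' can only arise from asymmetric modulation; such rows are removed before
#' fitting. The boundary value 1 is kept. The number of dropped rows is
#' reported as a message when nonzero.
#'
#' @param records measurement table.
#' @return the filtered table.
#' @export
filter_records <- function(records) {
  .check_schema(records)
  drop <- records$sensitivity < 1
  if (any(drop))
    message(sum(drop), " record(s) with sensitivity < 1 removed")
  records[!drop, , drop = FALSE]
}

#' Read / write measurement tables
#'
#' Comma-separated UTF-8 text with '.' decimal separator and a header row
#' naming at least the required columns: `dataset_id, L0, M0, S0, dL, dM,
#' dS, rho_cpd, omega_hz, area_deg2, ecc_deg, theta_deg, shape,
#' sensitivity`. `rho_cpd` may be empty/NA for disc rows. Unknown columns
#' are preserved untouched, and a write/read round trip is lossless. An
#' optional metadata file (same path with suffix `.meta.csv`, or given
#' explicitly) carries per-dataset rows: `dataset_id, n_observers, source,
#' is_reference`.
#'
#' @param path measurement CSV path.
#' @param meta_path optional dataset-metadata CSV path; defaults to
#'   `<path minus .csv>.meta.csv` and is only read if that file exists.
#' @return `read_measurements` returns a list with elements `records`
#'   (data.frame) and `metas` (data.frame or NULL).
#' @export
read_measurements <- function(path, meta_path = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(records)
  for (col in .schema_numeric) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row ",
             bad[1])
      records[[col]] <- conv
    }
  }
  allow_na <- c("rho_cpd")
  for (col in setdiff(.schema_numeric, allow_na))
    if (anyNA(records[[col]]))
      stop("missing value in column '", col, "' at data row ",
           which(is.na(records[[col]]))[1])
  if (!all(records$shape %in% c("gabor", "disc")))
    stop("shape must be 'gabor' or 'disc'")
  if (any(records$sensitivity <= 0))
    stop("sensitivity must be > 0")
  if (anyNA(records$rho_cpd[records$shape == "gabor"]))
    stop("Gabor rows must have a spatial frequency")
  if (is.null(meta_path)) {
    cand <- sub("\\.csv$", ".meta.csv", path)
    if (file.exists(cand) && cand != path) meta_path <- cand
  }
  metas <- if (!is.null(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else NULL
  list(records = records, metas = metas)
}

#' @rdname read_measurements
#' @param records measurement table to write.
#' @param metas optional dataset-metadata table.
#' @export
write_measurements <- function(records, path, metas = NULL) {
  .check_schema(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metas))
    utils::write.csv(metas, sub("\\.csv$", ".meta.csv", path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
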