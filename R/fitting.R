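# Joint fitting of model parameters and per-dataset sensitivity shifts to
# measurement tables, and cross-validated error evaluation in dB units.

# Parameters that enter the optimisation (the disc-extension constants are
# fixed by construction).
.fit_keys <- function() setdiff(.param_keys, c("disc.beta", "disc.a_disc"))

# Optimisation runs in an unconstrained space: log10 for
# positivity-constrained parameters and shifts, logit for the (0,1)-boxed
# truncation depths, identity for the transient-peak line coefficients.
.to_fit_space <- function(flat) {
  out <- flat
  for (k in names(flat)) {
    out[[k]] <- if (k %in% .param_free_sign) flat[[k]]
    else if (k %in% .param_unit_interval) stats::qlogis(flat[[k]])
    else log10(flat[[k]])
  }
  out
}

.from_fit_space <- function(theta) {
  out <- theta
  for (k in names(theta)) {
    out[[k]] <- if (k %in% .param_free_sign) theta[[k]]
    else if (k %in% .param_unit_interval) stats::plogis(theta[[k]])
    else 10^theta[[k]]
  }
  out
}

# Precompute everything about a record table that does not depend on the
# parameters, so the optimiser's objective is a few vectorised formula
# evaluations.
.prep_fit_data <- function(records) {
  .check_schema(records)
  n <- nrow(records)
  Y <- records$L0 + records$M0
  d <- rbind(records$dL, records$dM, records$dS)
  C <- (.dkl_matrix %*% d) / rep(Y, each = 3)
  sq <- function(dd, b) ifelse(dd == 0, 0, (dd / b)^2)
  cc <- sqrt(sq(records$dL, records$L0) + sq(records$dM, records$M0) +
               sq(records$dS, records$S0))
  gab <- which(records$shape != "disc")
  dsc <- which(records$shape == "disc")
  k <- length(.disc_rho_grid)
  # The disc grid-max is evaluated at the fixed reference area, so it only
  # depends on (omega, Y, ecc, theta): deduplicate those combinations.
  du <- NULL
  d_map <- integer(0)
  if (length(dsc)) {
    dd <- data.frame(omega = records$omega_hz[dsc], Y = Y[dsc],
                     ecc = records$ecc_deg[dsc],
                     theta = records$theta_deg[dsc])
    key <- do.call(paste, c(dd, sep = "\r"))
    uk <- !duplicated(key)
    du <- dd[uk, , drop = FALSE]
    d_map <- match(key, key[uk])
  }
  nu <- if (is.null(du)) 0L else nrow(du)
  list(n = n, C = C, cc = cc,
       obs_log = log10(records$sensitivity),
       dataset = as.character(records$dataset_id),
       gab = gab,
       g_rho = .effective_rho(records$rho_cpd[gab],
                              records$area_deg2[gab]),
       g_omega = records$omega_hz[gab], g_Y = Y[gab],
       g_area = records$area_deg2[gab], g_ecc = records$ecc_deg[gab],
       g_theta = records$theta_deg[gab],
       dsc = dsc, d_map = d_map,
       d_rho = rep(.disc_rho_grid, times = nu),
       d_omega = if (nu) rep(du$omega, each = k) else numeric(0),
       d_Y = if (nu) rep(du$Y, each = k) else numeric(0),
       d_ecc = if (nu) rep(du$ecc, each = k) else numeric(0),
       d_theta = if (nu) rep(du$theta, each = k) else numeric(0),
       d_area = records$area_deg2[dsc], d_k = k)
}

.predict_pre <- function(pre, params) {
  S <- matrix(0, 3, pre$n, dimnames = list(c("ach", "rg", "yv"), NULL))
  if (length(pre$gab))
    for (m in rownames(S))
      S[m, pre$gab] <- .mech_sensitivity(m, pre$g_rho, pre$g_omega, pre$g_Y,
                                         pre$g_area, pre$g_ecc, pre$g_theta,
                                         params)
  if (length(pre$dsc)) {
    fac <- (2 * pi * pre$d_area)^(1 / params$disc$beta)
    for (m in rownames(S)) {
      v <- .mech_sensitivity(m, pre$d_rho, pre$d_omega, pre$d_Y,
                             params$disc$a_disc, pre$d_ecc, pre$d_theta,
                             params)
      dim(v) <- c(pre$d_k, length(v) %/% pre$d_k)
      umax <- apply(v, 2L, max)
      S[m, pre$dsc] <- fac * umax[pre$d_map]
    }
  }
  E <- sqrt(colSums((S * pre$C)^2))
  E * sqrt(3) / pre$cc
}

#' Fitting configuration
#'
#' @param lambda_reg regularisation weight on `log10` per-dataset shifts
#'   (default 0.01).
#' @param reference_dataset_id dataset whose shift is fixed at exactly 1;
#'   defaults to the first dataset in the table.
#' @param lambda_scale `"none"` (penalty `lambda * sum`) or
#'   `"per_dataset"` (`lambda / D * sum`).
#' @param multistart number of optimisation starts: the first is the
#'   supplied initialisation, the rest are seeded jitters of +/- about
#'   `jitter_sd` log-units around it.
#' @param jitter_sd standard deviation of the multistart jitter in the
#'   transformed (log10/logit) space.
#' @param maxit,reltol quasi-Newton (BFGS) iteration cap and relative
#'   convergence tolerance.
#' @param seed integer seed controlling the multistart jitter.
#' @return list of class `csf_fit_config`.
#' @export
fit_config <- function(lambda_reg = 0.01, reference_dataset_id = NULL,
                       lambda_scale = c("none", "per_dataset"),
                       multistart = 5L, jitter_sd = 0.1,
                       maxit = 300L, reltol = 1e-10, seed = 1L) {
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  structure(list(lambda_reg = lambda_reg,
                 reference_dataset_id = reference_dataset_id,
                 lambda_scale = match.arg(lambda_scale),
                 multistart = as.integer(multistart),
                 jitter_sd = jitter_sd, maxit = as.integer(maxit),
                 reltol = reltol, seed = as.integer(seed)),
            class = "csf_fit_config")
}

#' Training loss
#'
#' `sum_d sum_i (log10 S_obs - log10(s_d * S_pred))^2 +
#'  lambda * sum_d (log10 s_d)^2`. Zero for perfect predictions with all
#' shifts at 1; a dataset-wide multiplicative offset in the data can be
#' absorbed by its shift at the cost of the penalty only.
#'
#' @param params a [csf_params()] object.
#' @param shifts named numeric vector of per-dataset shifts (> 0), one per
#'   dataset present in `records`; the reference dataset's shift must be 1.
#' @param records measurement table (already filtered).
#' @param config a [fit_config()].
#' @return nonnegative scalar loss.
#' @export
csf_loss <- function(params, shifts, records, config = fit_config()) {
  pre <- .prep_fit_data(records)
  ids <- unique(pre$dataset)
  if (!all(ids %in% names(shifts)))
    stop("missing shift for dataset(s): ",
         paste(setdiff(ids, names(shifts)), collapse = ", "))
  if (any(shifts <= 0)) stop("shifts must be > 0")
  pred <- .predict_pre(pre, csf_params(params))
  if (any(!is.finite(pred)) || any(pred <= 0))
    stop("model produced nonpositive or non-finite predictions")
  s <- shifts[pre$dataset]
  data_term <- sum((pre$obs_log - log10(s * pred))^2)
  lam <- config$lambda_reg
  if (config$lambda_scale == "per_dataset") lam <- lam / length(ids)
  data_term + lam * sum(log10(shifts[ids])^2)
}

#' Root-mean-square error in dB
#'
#' `20 * sqrt(mean((log10 S_obs - log10(s * S_pred))^2))`. A single point
#' mispredicted by a factor of 10 gives 20 dB; the value is invariant to
#' record order and to balanced duplication.
#'
#' @param observed observed sensitivities (> 0).
#' @param predicted model predictions, same length.
#' @param shifts per-record multiplicative shift (recycled; default 1).
#' @return error in dB.
#' @export
rmse_db <- function(observed, predicted, shifts = 1) {
  if (length(observed) == 0L) stop("empty input")
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  s <- rep_len(shifts, length(observed))
  20 * sqrt(mean((log10(observed) - log10(s * predicted))^2))
}

#' Per-dataset k-fold split
#'
#' Partitions the rows of each dataset into `k` near-equal folds by a
#' seeded shuffle; fold `j`'s test set is the union of the `j`-th parts
#' over datasets, so every fold sees every dataset (when large enough).
#' Datasets with fewer than `k` rows contribute all rows to training in the
#' folds they cannot reach, with a warning.
#'
#' @param records measurement table.
#' @param k number of folds (>= 2), default 5.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list of `k` lists with integer row-index vectors `train`,
#'   `test`.
#' @export
cv_splits <- function(records, k = 5L, seed = 1L) {
  .check_schema(records)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  ids <- as.character(records$dataset_id)
  fold <- integer(nrow(records))
  .with_seed(seed, {
    for (id in unique(ids)) {
      idx <- which(ids == id)
      if (length(idx) < k)
        warning("dataset '", id, "' has fewer than ", k,
                " records; some folds take all of them as training")
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  lapply(seq_len(k), function(j) {
    list(train = which(fold != j), test = which(fold == j))
  })
}

#' Fit the model jointly with per-dataset shifts
#'
#' Minimises [csf_loss()] over all mechanism parameters (in a transformed
#' space enforcing their constraints) and the `log10` shifts of all
#' non-reference datasets, using quasi-Newton (BFGS) descent with seeded
#' multistart. The best run is returned; the loss trace is the running
#' best objective value, hence nonincreasing.
#'
#' @param records measurement table (filter with [filter_records()] first).
#' @param config a [fit_config()].
#' @param init initial parameter set; default [default_params()].
#' @return object of class `csf_fit`: `params`, `shifts` (named, reference
#'   exactly 1), `final_loss`, `converged`, `loss_trace`, `reference`.
#' @export
csf_fit <- function(records, config = fit_config(),
                    init = default_params()) {
  init <- csf_params(init)
  pre <- .prep_fit_data(records)
  ids <- unique(pre$dataset)
  ref <- config$reference_dataset_id
  if (is.null(ref)) ref <- ids[1]
  if (!ref %in% ids)
    stop("reference dataset '", ref, "' not present in the data")
  free_ids <- setdiff(ids, ref)
  keys <- .fit_keys()
  theta0 <- unlist(.to_fit_space(as.list(params_to_vector(init)[keys])))
  if (length(free_ids))
    theta0 <- c(theta0, stats::setNames(rep(0, length(free_ids)),
                                        paste0("shift:", free_ids)))
  npar <- length(keys)
  lam <- config$lambda_reg
  if (config$lambda_scale == "per_dataset") lam <- lam / length(ids)
  template <- init
  trace_env <- new.env(parent = emptyenv())

  objective <- function(theta) {
    flat <- .from_fit_space(as.list(theta[seq_len(npar)]))
    names(flat) <- keys
    flat$disc.beta <- init$disc$beta
    flat$disc.a_disc <- init$disc$a_disc
    p <- .unflatten_params(flat)
    p$options <- template$options
    class(p) <- "csf_params"                 # transform guarantees validity
    pred <- .predict_pre(pre, p)
    if (any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
    log_s <- stats::setNames(rep(0, length(ids)), ids)
    if (length(free_ids))
      log_s[free_ids] <- theta[npar + seq_along(free_ids)]
    val <- sum((pre$obs_log - log_s[pre$dataset] - log10(pred))^2) +
      lam * sum(log_s^2)
    if (!is.finite(val)) return(1e10)
    trace_env$trace <- c(trace_env$trace, min(val, trace_env$best))
    trace_env$best <- min(val, trace_env$best)
    val
  }

  jitters <- .with_seed(config$seed, {
    lapply(seq_len(max(config$multistart, 1L)), function(i) {
      if (i == 1L) rep(0, length(theta0))
      else stats::rnorm(length(theta0), 0, config$jitter_sd)
    })
  })
  best <- NULL
  best_trace <- NULL
  for (jit in jitters) {
    trace_env$trace <- numeric(0)
    trace_env$best <- Inf
    res <- tryCatch(
      stats::optim(theta0 + jit, objective, method = "BFGS",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_trace <- trace_env$trace
    }
  }
  if (is.null(best))
    stop("all optimisation starts failed")
  flat <- .from_fit_space(as.list(best$par[seq_len(npar)]))
  names(flat) <- keys
  flat$disc.beta <- init$disc$beta
  flat$disc.a_disc <- init$disc$a_disc
  p <- .unflatten_params(flat)
  p$options <- template$options
  shifts <- stats::setNames(rep(1, length(ids)), ids)
  if (length(free_ids))
    shifts[free_ids] <- 10^best$par[npar + seq_along(free_ids)]
  structure(list(params = csf_params(p), shifts = shifts,
                 final_loss = best$value,
                 converged = best$convergence == 0L,
                 loss_trace = best_trace, reference = ref),
            class = "csf_fit")
}

#' @export
print.csf_fit <- function(x, ...) {
  cat(sprintf("<csf_fit> loss = %.6g (%s), %d dataset shift(s)\n",
              x$final_loss,
              if (x$converged) "converged" else "iteration cap reached",
              length(x$shifts)))
  for (id in names(x$shifts))
    cat(sprintf("  s[%s] = %.4g%s\n", id, x$shifts[[id]],
                if (id == x$reference) " (reference)" else ""))
  invisible(x)
}

#' Cross-validated model evaluation
#'
#' Five-fold (by default) cross-validation within each dataset: for each
#' fold the model and shifts are fitted on the training rows, the trained
#' shifts are reused for the same dataset's test rows (they are
#' dataset-level nuisance parameters, not predictions), and the test error
#' is reported with [rmse_db()].
#'
#' @param records measurement table (filtered).
#' @param config a [fit_config()]; its `seed` also fixes the fold split.
#' @param init initial parameters for every fold's fit.
#' @param k number of folds.
#' @return object of class `csf_eval`: `per_fold_db`, `mean_db`, `sd_db`,
#'   `n_points`, and the per-fold fits' shifts.
#' @export
cross_validate <- function(records, config = fit_config(),
                           init = default_params(), k = 5L) {
  splits <- cv_splits(records, k = k, seed = config$seed)
  per_fold <- numeric(length(splits))
  fold_shifts <- vector("list", length(splits))
  for (j in seq_along(splits)) {
    tr <- records[splits[[j]]$train, , drop = FALSE]
    te <- records[splits[[j]]$test, , drop = FALSE]
    fit <- csf_fit(tr, config = config, init = init)
    pred <- csf_predict(te, fit$params)
    sh <- fit$shifts[as.character(te$dataset_id)]
    sh[is.na(sh)] <- 1   # dataset absent from training: neutral shift
    per_fold[j] <- rmse_db(te$sensitivity, pred, sh)
    fold_shifts[[j]] <- fit$shifts
  }
  structure(list(per_fold_db = per_fold,
                 mean_db = mean(per_fold),
                 sd_db = stats::sd(per_fold),
                 n_points = nrow(records),
                 fold_shifts = fold_shifts),
            class = "csf_eval")
}

#' @export
print.csf_eval <- function(x, ...) {
  cat(sprintf("<csf_eval> %d points, %d folds: %.3f +/- %.3f dB\n",
              x$n_points, length(x$per_fold_db), x$mean_db, x$sd_db))
  cat("  per fold:", paste(sprintf("%.3f", x$per_fold_db), collapse = ", "),
      "dB\n")
  invisible(x)
}
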