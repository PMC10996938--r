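# Opponent-colour encoding: cone contrast, the fixed LMS -> DKL transform,
# and opponent contrast relative to background luminance.

# Fixed transform from cone-excitation increments to opponent increments
# (achromatic, red-green, yellow-violet). Derived for a D65 grey background
# and applied as a constant for all backgrounds; it is deliberately not
# re-derived per background, so a luminance modulation on a non-D65
# background may show cross-talk into the chromatic rows.
.dkl_matrix <- matrix(c( 1,  1,       0,
                         1, -2.3112,  0,
                        -1, -1,      50.9875),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("ach", "rg", "yv"),
                                      c("L", "M", "S")))

#' The fixed cone-increment to opponent-increment matrix
#'
#' @return 3x3 numeric matrix with rows `ach`, `rg`, `yv` and columns
#'   `L`, `M`, `S`.
#' @export
dkl_matrix <- function() .dkl_matrix

.check_triplet <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop(what, " must be a finite numeric triplet (L, M, S)")
  as.numeric(x)
}

.check_background <- function(bg) {
  bg <- .check_triplet(bg, "background")
  if (any(bg < 0)) stop("background cone excitations must be nonnegative")
  if (bg[1] + bg[2] <= 0) stop("background luminance L0 + M0 must be > 0")
  bg
}

#' RMS cone contrast of an increment over a background
#'
#' `sqrt(((dL/L0)^2 + (dM/M0)^2 + (dS/S0)^2) / 3)`. Model sensitivity is the
#' inverse of this quantity at the detection threshold.
#'
#' @param inc cone-excitation increment, numeric triplet `(dL, dM, dS)`.
#' @param bg background cone excitations `(L0, M0, S0)`, all > 0.
#' @return nonnegative scalar, homogeneous of degree 1 in `inc`.
#' @examples
#' bg <- d65_background(100)
#' cone_contrast(0.1 * bg, bg)  # 0.1
#' @export
cone_contrast <- function(inc, bg) {
  inc <- .check_triplet(inc, "increment")
  bg <- .check_triplet(bg, "background")
  zero <- which(bg == 0)
  if (length(zero))
    stop("background component ", paste(c("L0", "M0", "S0")[zero],
                                        collapse = ", "),
         " is zero; cone contrast undefined")
  sqrt(sum((inc / bg)^2) / 3)
}

#' Transform a cone increment to opponent increments
#'
#' Applies the fixed [dkl_matrix()] to `(dL, dM, dS)`, giving the increments
#' along the achromatic, red-green and yellow-violet opponent directions.
#' The map is linear.
#'
#' @param inc cone-excitation increment, numeric triplet.
#' @return named numeric vector `c(ach =, rg =, yv =)`.
#' @examples
#' lms_to_opponent(c(1, 0, 0))  # c(1, 1, -1)
#' @export
lms_to_opponent <- function(inc) {
  inc <- .check_triplet(inc, "increment")
  drop(.dkl_matrix %*% inc)
}

#' Opponent contrast of an opponent increment
#'
#' Divides each opponent increment by the background luminance
#' `Y = L0 + M0`.
#'
#' @param opp opponent increment, numeric triplet (ach, rg, yv).
#' @param bg background cone excitations `(L0, M0, S0)` with `L0 + M0 > 0`.
#' @return named numeric vector `c(ach =, rg =, yv =)`.
#' @export
opponent_contrast <- function(opp, bg) {
  opp <- .check_triplet(opp, "opponent increment")
  bg <- .check_background(bg)
  y <- bg[1] + bg[2]
  stats::setNames(opp / y, c("ach", "rg", "yv"))
}
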