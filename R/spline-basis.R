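#' Centered B-spline basis for the hospital fixed effect
#'
#' The smooth hospital-attribute effect f(V) is approximated by
#' f(V) = B(V)' gamma where B is a B-spline basis of degree d with q
#' equally spaced interior knots on the attribute mapped affinely to [0, 1]
#' (m_n = q + d + 1 basis functions).  Each column is centered by its mean
#' over the H hospitals used to build the basis, which enforces the
#' identifiability constraint E(f(V)) = 0 over the build sample for every
#' gamma (the model carries no separate fixed intercept; the random-effect
#' location plays that role).
#'
#' @param hospital_attrs Numeric vector: one attribute value per hospital.
#' @param d Spline degree (default 3, cubic).
#' @param q Number of interior knots (default 3).
#' @param knot_placement `"uniform"` (equally spaced on the mapped scale) or
#'   `"quantile"` (at empirical quantiles, for skewed attributes such as
#'   volume).
#' @return A `spline_basis` object with fields `degree`, `q`, `knots` (full
#'   knot vector on the [0,1] scale), `domain` (original-scale min/max used
#'   in the affine map), `centering_offsets` and `design` (the H x m_n
#'   centered basis evaluated at `hospital_attrs`).
#' @examples
#' sb <- build_basis(runif(50, -1, 1), d = 3, q = 3)
#' colMeans(sb$design)  # ~ 0 by construction
#' @export
build_basis <- function(hospital_attrs, d = 3L, q = 3L,
                        knot_placement = c("uniform", "quantile")) {
  knot_placement <- match.arg(knot_placement)
  v <- as.numeric(hospital_attrs)
  if (anyNA(v)) stop("'hospital_attrs' must not contain NA")
  d <- check_count(d, "d", min = 0L)
  q <- check_count(q, "q", min = 0L)
  rng <- range(v)
  if (diff(rng) <= 0) {
    stop("need at least 2 distinct hospital attribute values to build a basis")
  }
  m_n <- q + d + 1L
  if (length(v) < m_n) {
    warning(sprintf(
      "only %d hospitals for %d basis functions: design block is rank-deficient",
      length(v), m_n))
  }
  u <- (v - rng[1L]) / diff(rng)
  interior <- if (q > 0L) {
    if (knot_placement == "uniform") {
      seq(0, 1, length.out = q + 2L)[-c(1L, q + 2L)]
    } else {
      unname(stats::quantile(u, probs = seq_len(q) / (q + 1L), type = 7))
    }
  } else {
    numeric(0)
  }
  knots <- c(rep(0, d + 1L), interior, rep(1, d + 1L))
  raw <- splineDesign_clamped(knots, u, d)
  offsets <- colMeans(raw)
  spec <- structure(
    list(degree = d, q = q, knots = knots, domain = rng,
         knot_placement = knot_placement, centering_offsets = offsets,
         design = sweep(raw, 2L, offsets)),
    class = "spline_basis"
  )
  spec
}

## Uncentered basis on the [0,1] scale; values outside [0,1] are clamped to
## the boundary rather than extrapolated.
splineDesign_clamped <- function(knots, u, d) {
  u <- pmin(pmax(u, 0), 1)
  splines::splineDesign(knots, u, ord = d + 1L)
}

#' Evaluate the spline fixed effect f(v) = B(v)' gamma
#'
#' Attribute values are mapped with the affine map stored at build time;
#' values outside the build domain are clamped to the boundary.  The stored
#' centering offsets are subtracted so out-of-sample evaluations stay on the
#' same centered scale as the fit.
#'
#' @param spec A [build_basis()] object.
#' @param gamma Coefficient vector of length `q + degree + 1`.
#' @param v Attribute values on the original scale.
#' @return Numeric vector of f values.
#' @export
evaluate_f <- function(spec, gamma, v) {
  drop(basis_matrix(spec, v) %*% check_gamma(spec, gamma))
}

## centered basis rows at arbitrary original-scale attribute values
basis_matrix <- function(spec, v) {
  stopifnot(inherits(spec, "spline_basis"))
  u <- (as.numeric(v) - spec$domain[1L]) / diff(spec$domain)
  raw <- splineDesign_clamped(spec$knots, u, spec$degree)
  sweep(raw, 2L, spec$centering_offsets)
}

check_gamma <- function(spec, gamma) {
  m_n <- spec$q + spec$degree + 1L
  if (length(gamma) != m_n) {
    stop(sprintf("'gamma' must have length m_n = %d, got %d",
                 m_n, length(gamma)))
  }
  as.numeric(gamma)
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf(
    "Centered B-spline basis: degree %d, %d interior knots (%s), m_n = %d\n",
    x$degree, x$q, x$knot_placement, x$q + x$degree + 1L))
  cat(sprintf("  attribute domain [%.4g, %.4g], built on %d hospitals\n",
              x$domain[1L], x$domain[2L], nrow(x$design)))
  invisible(x)
}
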