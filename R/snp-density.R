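#' Semi-nonparametric (SNP) random-effect densities
#'
#' The hospital random effect \eqn{b} is modelled as \eqn{b = \sigma z + a}
#' where the standardized variable \eqn{z} has density proportional to
#' \eqn{P_K(z)^2 \phi(z)}, a squared polynomial of degree \eqn{K} times the
#' standard normal density.  Imposing \eqn{E[P_K(Z)^2] = 1} for standard
#' normal \eqn{Z} makes the density integrate to one, so
#' \deqn{g_K(b; \xi, a, \sigma) = P_K((b-a)/\sigma; \xi)\, N(b; a, \sigma^2).}
#' \eqn{K = 0} recovers the Gaussian \eqn{N(a, \sigma^2)}; larger \eqn{K}
#' admits skewed and multimodal shapes.  The constrained coefficient vector
#' \eqn{\xi} is parameterized by \eqn{K} free angles on the unit-quadratic
#' surface (see [angles_to_coefficients()]), which is what makes unconstrained
#' quasi-Newton maximum likelihood possible.
#'
#' @name snp-density
NULL

#' Raw-moment (Hermite) matrix of the standard normal
#'
#' Matrix \eqn{A} with \eqn{A_{ij} = E[Z^{i+j}]} for \eqn{Z \sim N(0,1)} and
#' 0-based indices \eqn{i, j = 0, \dots, K}: zero for odd \eqn{i+j} and the
#' double factorial \eqn{(i+j-1)!!} for even.  Encodes the normalization
#' constraint \eqn{\xi^\top A \xi = E[P_K(Z)^2] = 1}.
#'
#' @param K Non-negative integer truncation degree.
#' @return A symmetric positive-definite \eqn{(K+1)\times(K+1)} matrix.
#' @export
hermite_moment_matrix <- function(K) {
  K <- check_count(K, "K", min = 0L)
  m <- normal_raw_moments(2L * K)
  outer(0:K, 0:K, function(i, j) m[i + j + 1L])
}

## E[Z^m] for m = 0..mmax: 0 for odd m, (m-1)!! for even m.
normal_raw_moments <- function(mmax) {
  m <- numeric(mmax + 1L)
  m[1L] <- 1
  if (mmax >= 2L) {
    for (k in seq(2L, mmax, by = 2L)) m[k + 1L] <- m[k - 1L] * (k - 1)
  }
  m
}

#' Map free angles to constrained SNP polynomial coefficients
#'
#' Hyperspherical transform: the angles determine a unit vector
#' \eqn{c \in S^K} (\eqn{c_0 = \prod_k \cos\varphi_k},
#' \eqn{c_k = \sin\varphi_k \prod_{l>k} \cos\varphi_l}) and
#' \eqn{\xi = A^{-1/2} c} with \eqn{A^{1/2}} the symmetric PSD square root of
#' [hermite_moment_matrix()], so \eqn{\xi^\top A \xi = 1} by construction.
#' Since \eqn{\xi} and \eqn{-\xi} give the same density, the sign is fixed by
#' \eqn{\xi_0 \ge 0}.
#'
#' @param angles Numeric vector of length \eqn{K}, each in
#'   \eqn{(-\pi/2, \pi/2]}.  Length 0 gives the Gaussian case \eqn{\xi = 1}.
#' @return Numeric coefficient vector \eqn{\xi} of length \eqn{K+1}.
#' @export
angles_to_coefficients <- function(angles) {
  angles <- as.numeric(angles)
  if (anyNA(angles)) stop("'angles' must not contain NA")
  if (any(angles <= -pi / 2 | angles > pi / 2)) {
    stop("each angle must lie in (-pi/2, pi/2]")
  }
  K <- length(angles)
  if (K == 0L) return(1)
  ## unit vector on S^K from hyperspherical coordinates
  cosprod <- rev(cumprod(rev(cos(angles))))        # prod_{l >= k} cos
  cvec <- c(cosprod[1L], sin(angles) * c(cosprod[-1L], 1))
  xi <- drop(matrix_inv_sqrt(hermite_moment_matrix(K)) %*% cvec)
  if (xi[1L] < 0) xi <- -xi
  xi
}

## symmetric inverse square root of an SPD matrix
matrix_inv_sqrt <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Construct SNP density parameters
#'
#' @param K Truncation degree (non-negative integer).
#' @param a Location (the Gaussian base mean; plays the role of the model
#'   intercept).
#' @param sigma Scale, must be positive.
#' @param angles Numeric vector of length `K` in \eqn{(-\pi/2, \pi/2]}.
#' @return An object of class `snp_params` with fields `K`, `a`, `sigma`,
#'   `angles` and the derived constrained coefficients `xi`.
#' @examples
#' p <- snp_params(K = 2, a = 0, sigma = 1, angles = c(0.3, -0.4))
#' integrate(snp_pdf, -Inf, Inf, params = p)
#' @export
snp_params <- function(K = 0L, a = 0, sigma = 1, angles = numeric(0)) {
  K <- check_count(K, "K", min = 0L)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a positive finite number")
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a)) {
    stop("'a' must be a finite number")
  }
  if (length(angles) != K) stop("'angles' must have length K")
  xi <- angles_to_coefficients(angles)
  structure(
    list(K = K, a = a, sigma = sigma, angles = as.numeric(angles), xi = xi),
    class = "snp_params"
  )
}

#' @export
print.snp_params <- function(x, ...) {
  cat("SNP random-effect density g_K(b; xi, a, sigma)\n")
  cat(sprintf("  K = %d, a = %.4g, sigma = %.4g\n", x$K, x$a, x$sigma))
  cat("  xi =", paste(signif(x$xi, 4), collapse = ", "), "\n")
  mo <- snp_moments(x)
  cat(sprintf("  E(b) = %.4g, Var(b) = %.4g\n", mo[["mean"]], mo[["variance"]]))
  invisible(x)
}

## P_K(z) = sum_j xi_j z^j, vectorized over z
snp_polynomial <- function(z, xi) {
  acc <- rep(xi[length(xi)], length(z))
  if (length(xi) > 1L) {
    for (j in seq(length(xi) - 1L, 1L)) acc <- acc * z + xi[j]
  }
  acc
}

#' SNP probability density
#'
#' Evaluates \eqn{g_K(b) = P_K((b-a)/\sigma)^2 N(b; a, \sigma^2)}.
#'
#' @param b Numeric vector of evaluation points.
#' @param params An [snp_params()] object.
#' @param log Return the log density?
#' @return Density values (nonnegative; integrate to 1).
#' @export
snp_pdf <- function(b, params, log = FALSE) {
  stopifnot(inherits(params, "snp_params"))
  z <- (b - params$a) / params$sigma
  p <- snp_polynomial(z, params$xi)
  if (log) {
    2 * base::log(abs(p)) + stats::dnorm(b, params$a, params$sigma, log = TRUE)
  } else {
    p^2 * stats::dnorm(b, params$a, params$sigma)
  }
}

#' Mean and variance of an SNP density
#'
#' Closed form through Gaussian raw moments:
#' \eqn{E[z^m] = \sum_{i,j} \xi_i \xi_j E[Z^{i+j+m}]}, then
#' \eqn{E[b] = a + \sigma E[z]} and
#' \eqn{Var(b) = \sigma^2 (E[z^2] - E[z]^2)}.
#'
#' @param params An [snp_params()] object.
#' @return Named numeric vector `c(mean =, variance =)`.
#' @export
snp_moments <- function(params) {
  stopifnot(inherits(params, "snp_params"))
  xi <- params$xi
  K <- params$K
  m <- normal_raw_moments(2L * K + 2L)
  zmom <- function(ord) {
    sum(outer(0:K, 0:K, function(i, j) m[i + j + ord + 1L]) * tcrossprod(xi))
  }
  ez <- zmom(1L)
  ez2 <- zmom(2L)
  c(mean = params$a + params$sigma * ez,
    variance = params$sigma^2 * (ez2 - ez^2))
}

#' Draw from an SNP density
#'
#' Numeric inverse-CDF sampling: the density is tabulated on a 10,001-point
#' grid over \eqn{[a - 10\sigma, a + 10\sigma]}, integrated by the trapezoid
#' rule, and uniform draws are mapped through linear interpolation of the
#' inverse CDF.
#'
#' @param params An [snp_params()] object.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n`.
#' @export
snp_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "snp_params"))
  n <- check_count(n, "n", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(params$a - 10 * params$sigma, params$a + 10 * params$sigma,
              length.out = 10001L)
  dens <- snp_pdf(grid, params)
  cdf <- cumsum(c(0, (dens[-1L] + dens[-length(dens)]) / 2)) * diff(grid[1:2])
  cdf <- cdf / cdf[length(cdf)]
  ## guard against flat CDF stretches (density zeros): keep strictly increasing
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], grid[keep], xout = stats::runif(n),
                rule = 2, ties = "ordered")$y
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
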