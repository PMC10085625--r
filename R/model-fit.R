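#' Marginal likelihood of hospital compare additive models
#'
#' Two model families share one marginal likelihood machinery:
#'
#' * HCAM: logit(p_hj) = b_h + B(V_h)' gamma + X_hj' beta, with the hospital
#'   random effect b_h ~ g_K (an SNP density, [snp_params()]).
#' * ZI-HCAM: a latent at-risk status S_hj with logit(rho_hj) = T_hj' theta
#'   multiplies the at-risk mortality pi_hj (same linear predictor as HCAM),
#'   so P(Y = 1) = rho * pi.  Writing tau = T'theta and kappa for the HCAM
#'   linear predictor, each patient contributes
#'   Y (tau + kappa) + (1 - Y) log(1 + e^tau + e^kappa)
#'   - log(1 + e^tau) - log(1 + e^kappa)
#'   to the conditional log likelihood, which equals log(rho pi) for Y = 1
#'   and log(1 - rho pi) for Y = 0.
#'
#' Each hospital's one-dimensional integral over b is evaluated by adaptive
#' Gauss-Hermite quadrature: nodes are centered and scaled at the mode and
#' curvature of the Bernoulli-times-Gaussian-base part of the log integrand
#' (a concave function, so the Newton mode search is safe) and the squared
#' SNP polynomial is folded into the integrand at the nodes.  Sums over
#' nodes use log-sum-exp.
#'
#' @name hcam-likelihood
NULL

log1pexp <- function(x) {
  ax <- abs(x)
  (x + ax) / 2 + log1p(exp(-ax))
}

inv_logit <- function(x) 1 / (1 + exp(-x))

## log(1 + e^tau + e^kappa), elementwise, overflow-safe
log1p2exp <- function(tau, kappa) {
  m <- pmax(0, tau, kappa)
  m + log(exp(-m) + exp(tau - m) + exp(kappa - m))
}

## Per-patient conditional loglik and its first two derivatives in kappa.
## tau = NULL selects the plain Bernoulli (HCAM) terms.
patient_terms <- function(kappa, y, tau = NULL, order = 0L) {
  if (is.null(tau)) {
    if (order == 0L) return(y * kappa - log1pexp(kappa))
    p <- inv_logit(kappa)
    if (order == 1L) return(y - p)
    return(-p * (1 - p))
  }
  if (order == 0L) {
    out <- log1p2exp(tau, kappa)                       # Y = 0 branch
    out[y == 1] <- (tau + kappa)[y == 1]
    return(out - log1pexp(tau) - log1pexp(kappa))
  }
  p <- inv_logit(kappa)
  w <- exp(kappa - log1p2exp(tau, kappa))              # e^k/(1+e^t+e^k)
  if (order == 1L) {
    d <- w - p
    d[y == 1] <- (1 - p)[y == 1]
    return(d)
  }
  d2 <- w * (1 - w) - p * (1 - p)
  d2[y == 1] <- (-p * (1 - p))[y == 1]
  d2
}

## Internal: everything the optimizer needs precomputed once per fit.
likelihood_context <- function(data, basis, n_quad) {
  gh <- pracma::gaussHermite(n_quad)
  ## rows sorted by hospital so cluster sums are contiguous-segment sums
  ord <- order(data$hospital)
  idx <- data$hospital[ord]
  list(
    idx = idx, H = data$H, y = data$y[ord], X = data$X[ord, , drop = FALSE],
    T_mat = if (!is.null(data$T_mat)) data$T_mat[ord, , drop = FALSE],
    Bpat = basis$design[idx, , drop = FALSE],
    m_n = basis$q + basis$degree + 1L,
    seg_ends = cumsum(data$n_h),
    gh_x = gh$x, gh_logw = log(gh$w) + gh$x^2,
    mode_cache = new.env(parent = emptyenv())
  )
}

## per-hospital sums of a patient-level vector or matrix over sorted rows
group_sum <- function(ctx, x) {
  if (is.matrix(x)) {
    cs <- apply(x, 2L, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow(x), ncol(x))  # 1-row input
    s <- cs[ctx$seg_ends, , drop = FALSE]
    s - rbind(0, s[-ctx$H, , drop = FALSE])
  } else {
    cs <- cumsum(x)[ctx$seg_ends]
    c(cs[1L], diff(cs))
  }
}

## Adaptive-quadrature marginal log likelihood given unpacked parameters.
## xi enters only through the polynomial factor at the nodes.
agq_loglik <- function(ctx, beta, gamma, a, sigma, xi, theta = NULL,
                       per_hospital = FALSE) {
  offset <- drop(ctx$X %*% beta) + drop(ctx$Bpat %*% gamma)
  tau <- if (is.null(theta)) NULL else drop(ctx$T_mat %*% theta)
  if (any(!is.finite(offset)) || (!is.null(tau) && any(!is.finite(tau)))) {
    bad <- unique(ctx$idx[!is.finite(offset)])
    stop("non-finite linear predictor for hospital index ",
         paste(utils::head(bad, 3L), collapse = ", "))
  }
  idx <- ctx$idx; H <- ctx$H; y <- ctx$y

  ## -- mode of the concave part: sum_j l_j(b + offset_j) + log N(b; a, s2)
  b <- ctx$mode_cache$modes
  if (is.null(b) || length(b) != H) b <- rep(a, H)
  qfun <- function(b) {
    group_sum(ctx, patient_terms(b[idx] + offset, y, tau)) +
      stats::dnorm(b, a, sigma, log = TRUE)
  }
  qb <- qfun(b)
  for (it in seq_len(30L)) {
    kappa <- b[idx] + offset
    g <- group_sum(ctx, patient_terms(kappa, y, tau, 1L)) -
      (b - a) / sigma^2
    h <- group_sum(ctx, patient_terms(kappa, y, tau, 2L)) - 1 / sigma^2
    h <- pmin(h, -1e-8)
    step <- -g / h
    step <- pmin(pmax(step, -4 * sigma), 4 * sigma)
    bnew <- b + step
    qnew <- qfun(bnew)
    for (halve in seq_len(8L)) {       # safeguard: never step downhill
      worse <- qnew < qb - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      bnew <- b + step
      qnew <- qfun(bnew)
    }
    moved <- max(abs(bnew - b))
    b <- bnew; qb <- qnew
    if (moved < 1e-8 * sigma && max(abs(g)) < 1e-6) break
  }
  ctx$mode_cache$modes <- b
  kappa <- b[idx] + offset
  h <- group_sum(ctx, patient_terms(kappa, y, tau, 2L)) - 1 / sigma^2
  s <- 1 / sqrt(-pmin(h, -1e-8))

  ## -- quadrature: b_hk = mode_h + sqrt(2) s_h x_k, all nodes in one pass
  nq <- length(ctx$gh_x)
  bk <- outer(sqrt(2) * s, ctx$gh_x) + b              # H x nq
  z <- (bk - a) / sigma
  logint <- group_sum(ctx, patient_terms(bk[idx, , drop = FALSE] + offset,
                                         y, tau)) +
    stats::dnorm(bk, a, sigma, log = TRUE) +
    2 * log(abs(snp_polynomial(z, xi))) +
    rep(ctx$gh_logw, each = H)
  mrow <- apply(logint, 1L, max)
  ll_h <- log(sqrt(2) * s) + mrow + log(rowSums(exp(logint - mrow)))
  if (per_hospital) ll_h else sum(ll_h)
}

#' HCAM marginal log likelihood
#'
#' @param data A [hospital_data()] object.
#' @param params A list with elements `beta`, `gamma`, `snp` (an
#'   [snp_params()] object) and, for the zero-inflated model, `theta`.
#' @param basis A [build_basis()] object (built on `data$V`).
#' @param n_quad Number of adaptive Gauss-Hermite nodes (>= 3).
#' @return The marginal log likelihood (a scalar).
#' @export
hcam_marginal_loglik <- function(data, params, basis, n_quad = 21L) {
  marginal_loglik(data, params, basis, n_quad, zib = FALSE)
}

#' ZIB marginal log likelihood
#'
#' @inheritParams hcam_marginal_loglik
#' @export
zib_marginal_loglik <- function(data, params, basis, n_quad = 21L) {
  if (is.null(data$T_mat)) stop("zero-inflated model requires T covariates")
  if (is.null(params$theta)) stop("zero-inflated model requires 'theta'")
  marginal_loglik(data, params, basis, n_quad, zib = TRUE)
}

marginal_loglik <- function(data, params, basis, n_quad, zib) {
  stopifnot(inherits(data, "hospital_data"), inherits(basis, "spline_basis"),
            inherits(params$snp, "snp_params"))
  n_quad <- check_count(n_quad, "n_quad", min = 3L)
  ctx <- likelihood_context(data, basis, n_quad)
  if (length(params$beta) != ncol(data$X)) stop("'beta' has wrong length")
  gamma <- check_gamma(basis, params$gamma)
  agq_loglik(ctx, as.numeric(params$beta), gamma, params$snp$a,
             params$snp$sigma, params$snp$xi,
             theta = if (zib) as.numeric(params$theta) else NULL)
}

## ---- parameter packing ----------------------------------------------------

pack_params <- function(beta, gamma, a, log_sigma, angles, theta = NULL) {
  c(beta, gamma, a, log_sigma, angles, theta)
}

unpack_params <- function(par, px, m_n, K, pt = 0L) {
  i <- 0L
  take <- function(n) {
    out <- par[i + seq_len(n)]; i <<- i + n; out
  }
  list(beta = take(px), gamma = take(m_n), a = take(1L),
       log_sigma = take(1L), angles = take(K),
       theta = if (pt > 0L) take(pt) else NULL)
}

## unchecked angle map used inside the optimizer (any real angle is a valid
## point on the sphere; the canonical wrapped form is recovered afterwards)
angles_to_xi_free <- function(angles, Ahalf_inv) {
  K <- length(angles)
  if (K == 0L) return(1)
  cosprod <- rev(cumprod(rev(cos(angles))))
  cvec <- c(cosprod[1L], sin(angles) * c(cosprod[-1L], 1))
  xi <- drop(Ahalf_inv %*% cvec)
  if (xi[1L] < 0) xi <- -xi
  xi
}

## canonical angles in (-pi/2, pi/2] from a constrained xi
canonical_angles <- function(xi) {
  K <- length(xi) - 1L
  if (K == 0L) return(numeric(0))
  A <- hermite_moment_matrix(K)
  e <- eigen(A, symmetric = TRUE)
  cvec <- drop(e$vectors %*% (t(e$vectors) * sqrt(e$values)) %*% xi)
  cvec <- cvec / sqrt(sum(cvec^2))
  if (cvec[1L] < 0) cvec <- -cvec
  ang <- numeric(K)
  denom <- 1
  for (k in seq(K, 1L)) {
    sk <- max(-1, min(1, cvec[k + 1L] / denom))
    ang[k] <- asin(sk)
    denom <- denom * cos(ang[k])
    if (abs(denom) < 1e-12) denom <- 1e-12
  }
  ang[ang <= -pi / 2] <- pi / 2
  ang
}

## ---- fitting --------------------------------------------------------------

#' Fit a hospital compare additive model by maximum likelihood
#'
#' Maximizes the adaptive-quadrature marginal likelihood by quasi-Newton
#' (BFGS with central-difference numerical gradients) for each truncation
#' degree in `K_grid` (ascending).  K = 0 is warm-started from a
#' no-random-effect logistic fit with sigma = 1; each larger K is
#' warm-started from the previous solution with the new angle at 0.  The
#' reported model is the BIC minimizer (ties go to the smaller K).
#'
#' @param data A [hospital_data()] object.
#' @param model `"hcam"` or `"zib"` (the latter needs `data$T_mat`).
#' @param d,q Spline degree and interior-knot count for the hospital
#'   attribute effect (defaults 3 and 3).
#' @param K_grid Integer vector of SNP truncation degrees to try
#'   (default 0:3).
#' @param n_quad Adaptive Gauss-Hermite nodes (default 21).
#' @param knot_placement Passed to [build_basis()].
#' @param control List: `maxit` (default 500), `reltol` (default 1e-8).
#' @param warn_no_event Warn about hospitals with no outcome variation
#'   (default TRUE).  Such hospitals are kept; dropping them is a loading
#'   choice (see [load_dataset()]).
#' @return An object of class `hcam_fit` for the selected K, with fields
#'   `params` (beta, gamma, snp, theta), `basis`, `loglik`, `aic`, `bic`
#'   (p = number of free parameters, BIC uses log N over patients),
#'   `converged`, `iterations`, `n_quad`, `random_effect_mean`,
#'   `random_effect_variance`, `b_modes` (per-hospital empirical-Bayes
#'   posterior modes), `K_table` (one row per K tried) and `fits` (all
#'   per-K fits).
#' @examples
#' \donttest{
#' sim <- simulate_hospital_data(scenario_spec(H = 40, n_h = 20, seed = 1))
#' fit <- fit_hcam(sim$data, K_grid = 0, n_quad = 9)
#' fit
#' }
#' @export
fit_hcam <- function(data, model = c("hcam", "zib"), d = 3L, q = 3L,
                     K_grid = 0:3, n_quad = 21L,
                     knot_placement = "uniform",
                     control = list(), warn_no_event = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "hospital_data"))
  zib <- model == "zib"
  if (zib && is.null(data$T_mat)) stop("model = 'zib' requires T covariates")
  K_grid <- sort(unique(vapply(K_grid, check_count, integer(1), name = "K")))
  n_quad <- check_count(n_quad, "n_quad", min = 3L)
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-8), control)
  if (warn_no_event) {
    novar <- tapply(data$y, data$hospital, function(z) length(unique(z)) == 1L)
    if (any(novar)) {
      warning(sum(novar), " hospital(s) have no outcome variation; their ",
              "random effects are weakly identified")
    }
  }
  basis <- build_basis(data$V, d = d, q = q, knot_placement = knot_placement)
  ctx <- likelihood_context(data, basis, n_quad)
  px <- ncol(data$X); m_n <- ctx$m_n
  pt <- if (zib) ncol(data$T_mat) else 0L

  ## warm start from a no-random-effect logistic fit
  g0 <- stats::glm.fit(cbind(1, data$X, ctx$Bpat), data$y,
                       family = stats::binomial())
  co <- g0$coefficients
  co[!is.finite(co)] <- 0
  start <- list(beta = co[1L + seq_len(px)], gamma = co[1L + px + seq_len(m_n)],
                a = co[1L], log_sigma = 0, xi = 1,
                theta = if (zib) c(2, rep(0, pt - 1L)) else NULL)
  if (zib) {
    ## refine with a no-random-effect ZIB fit (closed form, no integration):
    ## p = logit^{-1}(T'theta) * logit^{-1}(a + B'gamma + X'beta)
    nore <- function(par) {
      beta <- par[seq_len(px)]
      gamma <- par[px + seq_len(m_n)]
      a <- par[px + m_n + 1L]
      theta <- par[px + m_n + 1L + seq_len(pt)]
      tau <- drop(ctx$T_mat %*% theta)
      kap <- a + drop(ctx$X %*% beta) + drop(ctx$Bpat %*% gamma)
      ll <- sum(ifelse(ctx$y == 1, tau + kap, log1p2exp(tau, kap)) -
                  log1pexp(tau) - log1pexp(kap))
      if (!is.finite(ll)) 1e10 else -ll
    }
    o0 <- stats::optim(c(start$beta, start$gamma, start$a, start$theta),
                       nore, method = "BFGS", control = list(maxit = 300L))
    start$beta <- o0$par[seq_len(px)]
    start$gamma <- o0$par[px + seq_len(m_n)]
    start$a <- o0$par[px + m_n + 1L]
    start$theta <- o0$par[px + m_n + 1L + seq_len(pt)]
  }

  fits <- vector("list", length(K_grid))
  names(fits) <- paste0("K", K_grid)
  prev <- start
  for (ik in seq_along(K_grid)) {
    K <- K_grid[ik]
    Ahalf_inv <- if (K > 0L) matrix_inv_sqrt(hermite_moment_matrix(K))
    ## nested warm start: pad the previous xi with zero top coefficients
    ## (stays on the constraint surface, so the start reproduces the K-1
    ## density exactly and loglik can only improve)
    xi0 <- c(prev$xi, rep(0, K + 1L - length(prev$xi)))
    angles0 <- canonical_angles(xi0)
    negll <- function(par) {
      up <- unpack_params(par, px, m_n, K, pt)
      sigma <- exp(up$log_sigma)
      if (!is.finite(sigma) || sigma <= 0 || sigma > 50) return(1e10)
      xi <- angles_to_xi_free(up$angles, Ahalf_inv)
      ll <- tryCatch(
        agq_loglik(ctx, up$beta, up$gamma, up$a, sigma, xi, up$theta),
        error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    grad <- function(par) num_grad_central(negll, par)
    ## the previous-K solution is a stationary point of the richer model
    ## (its tangent angle directions coincide with mean/variance shifts
    ## already optimized through a and sigma), so quasi-Newton cannot leave
    ## it; perturbed-angle starts let the polynomial shape escape, and the
    ## unperturbed start guarantees loglik is nested in K
    offsets <- if (K > 0L) c(0, 0.35, -0.35) else 0
    opt <- NULL
    for (eps in offsets) {
      ang_s <- pmin(pmax(angles0 + eps, -pi / 2 + 0.01), pi / 2 - 0.01)
      par0 <- pack_params(prev$beta, prev$gamma, prev$a, prev$log_sigma,
                          ang_s, prev$theta)
      o <- stats::optim(par0, negll, gr = grad, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
    up <- unpack_params(opt$par, px, m_n, K, pt)
    sigma <- exp(up$log_sigma)
    xi <- angles_to_xi_free(up$angles, Ahalf_inv)
    snp <- snp_params(K = K, a = up$a, sigma = sigma,
                      angles = canonical_angles(xi))
    p_free <- length(opt$par)
    ll <- -opt$value
    mo <- snp_moments(snp)
    fits[[ik]] <- structure(list(
      model = model,
      params = list(beta = unname(up$beta), gamma = unname(up$gamma),
                    snp = snp, theta = unname(up$theta)),
      basis = basis, loglik = ll,
      aic = -2 * ll + 2 * p_free,
      bic = -2 * ll + p_free * log(data$N),
      n_params = p_free, n_quad = n_quad,
      converged = opt$convergence == 0L,
      iterations = unname(opt$counts[1L]),
      random_effect_mean = unname(mo[["mean"]]),
      random_effect_variance = unname(mo[["variance"]]),
      K = K
    ), class = "hcam_fit")
    prev <- list(beta = up$beta, gamma = up$gamma, a = up$a,
                 log_sigma = up$log_sigma, xi = xi, theta = up$theta)
    if (!fits[[ik]]$converged) {
      warning(sprintf("fit for K = %d did not converge", K))
    }
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- fits[[which.min(bics)]]           # which.min: ties -> smaller K
  sel$K_table <- data.frame(
    K = K_grid,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = bics,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL
  )
  sel$fits <- fits
  sel$b_modes <- posterior_modes(sel, data)
  sel
}

## central differences, step 1e-6 on unit scale
num_grad_central <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    hp <- h * max(1, abs(par[i]))
    e <- replace(numeric(length(par)), i, hp)
    (f(par + e) - f(par - e)) / (2 * hp)
  }, numeric(1))
}

#' @export
print.hcam_fit <- function(x, ...) {
  cat(sprintf("%s fit (SNP K = %d, %d quadrature nodes)\n",
              toupper(x$model), x$K, x$n_quad))
  cat(sprintf("  logLik %.3f, AIC %.2f, BIC %.2f, %sconverged in %d iters\n",
              x$loglik, x$aic, x$bic, if (x$converged) "" else "NOT ",
              x$iterations))
  cat("  beta:", paste(signif(x$params$beta, 4), collapse = ", "), "\n")
  if (!is.null(x$params$theta)) {
    cat("  theta:", paste(signif(x$params$theta, 4), collapse = ", "), "\n")
  }
  cat(sprintf("  random effect: E(b) = %.4f, Var(b) = %.4f\n",
              x$random_effect_mean, x$random_effect_variance))
  if (!is.null(x$K_table)) {
    cat("  K selection (BIC):\n")
    print(x$K_table, row.names = FALSE)
  }
  invisible(x)
}

#' Per-hospital empirical-Bayes random effects
#'
#' Posterior modes of b_h given the hospital's data under the fitted SNP
#' density (grid argmax over mode +/- 8 posterior SDs with parabolic
#' refinement; the posterior can be multimodal when K > 0, which rules out
#' plain Newton).  `posterior_means` integrates b against the same
#' posterior with adaptive quadrature.
#'
#' @param fit An `hcam_fit` object.
#' @param data The dataset the model was fitted to.
#' @return Numeric vector of length H.
#' @export
posterior_modes <- function(fit, data) {
  pp <- posterior_profile(fit, data)
  best <- max.col(pp$logpost, ties.method = "first")
  H <- nrow(pp$logpost); ng <- ncol(pp$logpost)
  b <- pp$bgrid[cbind(seq_len(H), best)]
  ## parabola through the argmax and neighbours
  inner <- best > 1L & best < ng
  if (any(inner)) {
    i <- which(inner)
    y0 <- pp$logpost[cbind(i, best[i] - 1L)]
    y1 <- pp$logpost[cbind(i, best[i])]
    y2 <- pp$logpost[cbind(i, best[i] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
    b[i] <- b[i] + pmin(pmax(shift, -1), 1) * pp$step[i]
  }
  b
}

#' @rdname posterior_modes
#' @export
posterior_means <- function(fit, data) {
  pp <- posterior_profile(fit, data)
  w <- exp(pp$logpost - apply(pp$logpost, 1L, max))
  rowSums(w * pp$bgrid) / rowSums(w)
}

## dense per-hospital profile of the unnormalized log posterior of b_h
posterior_profile <- function(fit, data, ngrid = 241L) {
  stopifnot(inherits(fit, "hcam_fit"), inherits(data, "hospital_data"))
  ctx <- likelihood_context(data, fit$basis, fit$n_quad)
  snp <- fit$params$snp
  theta <- fit$params$theta
  offset <- drop(ctx$X %*% fit$params$beta) + drop(ctx$Bpat %*% fit$params$gamma)
  tau <- if (is.null(theta)) NULL else drop(ctx$T_mat %*% theta)
  ## center the grid with one likelihood pass (fills the mode cache)
  agq_loglik(ctx, fit$params$beta, fit$params$gamma, snp$a, snp$sigma,
             snp$xi, theta)
  mu <- ctx$mode_cache$modes
  half <- 8 * snp$sigma
  step <- rep(2 * half / (ngrid - 1L), data$H)
  bgrid <- outer(mu - half, seq(0, 2 * half, length.out = ngrid), `+`)
  logpost <- group_sum(ctx, patient_terms(
    bgrid[ctx$idx, , drop = FALSE] + offset, ctx$y, tau)) +
    snp_pdf(bgrid, snp, log = TRUE)
  list(bgrid = bgrid, logpost = logpost, step = step)
}

#' Predicted mortality probabilities
#'
#' HCAM: logit^{-1}(b_H + f(V_H) + X' beta) with b_H the hospital's
#' empirical-Bayes mode; ZI-HCAM multiplies by rho = logit^{-1}(T' theta).
#'
#' @param fit An `hcam_fit` object with `b_modes` (as returned by
#'   [fit_hcam()]).
#' @param X Covariate matrix (rows = patients to predict).
#' @param hospital Hospital index (1..H as fitted) at which every row is
#'   evaluated, or a vector of per-row indices.
#' @param T_mat Zero-inflation covariates, required for ZIB fits.
#' @param data The fitted dataset (supplies V and b modes' alignment).
#' @return Vector of probabilities in (0, 1).
#' @export
predict_mortality <- function(fit, X, hospital, data, T_mat = NULL) {
  stopifnot(inherits(fit, "hcam_fit"))
  X <- as.matrix(X)
  hospital <- as.integer(hospital)
  if (any(hospital < 1L | hospital > data$H)) stop("invalid hospital index")
  if (length(hospital) == 1L) hospital <- rep(hospital, nrow(X))
  fv <- evaluate_f(fit$basis, fit$params$gamma, data$V)
  eta <- fit$b_modes[hospital] + fv[hospital] + drop(X %*% fit$params$beta)
  p <- stats::plogis(eta)
  if (fit$model == "zib") {
    if (is.null(T_mat)) stop("ZIB predictions require 'T_mat'")
    p <- p * stats::plogis(drop(as.matrix(T_mat) %*% fit$params$theta))
  }
  p
}
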