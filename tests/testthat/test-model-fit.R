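test_that("AGQ marginal loglik matches dense trapezoid integration on a tiny cluster", {
  dat <- toy_dataset()
  basis <- build_basis(dat$V, d = 1, q = 0)
  beta <- c(0.5, -0.3, 0.2); gamma <- c(0.1, -0.1); theta <- c(0.4, -0.6)
  for (K in 0:2) {
    ang <- if (K == 0) numeric(0) else seq(0.3, by = -0.5, length.out = K)
    snp <- snp_params(K = K, a = 0.2, sigma = 0.8, angles = ang)
    pars <- list(beta = beta, gamma = gamma, snp = snp, theta = theta)

    ll_zib <- zib_marginal_loglik(dat, pars, basis, n_quad = 21)
    oracle_zib <- trapezoid_marginal_loglik(dat, pars, basis)
    expect_equal(ll_zib, oracle_zib, tolerance = 1e-6)

    pars_h <- pars[c("beta", "gamma", "snp")]
    ll_h <- hcam_marginal_loglik(dat, pars_h, basis, n_quad = 21)
    oracle_h <- trapezoid_marginal_loglik(dat, pars_h, basis)
    expect_equal(ll_h, oracle_h, tolerance = 1e-6)
  }
})

test_that("ZIB loglik reduces to HCAM when rho is forced to 1", {
  dat <- toy_dataset()
  basis <- build_basis(dat$V, d = 1, q = 0)
  pars <- list(beta = c(0.5, -0.3, 0.2), gamma = c(0.1, -0.1),
               snp = snp_params(K = 0, a = 0.2, sigma = 0.8),
               theta = c(30, 0))   # logit(rho) = 30 => rho ~ 1
  expect_equal(zib_marginal_loglik(dat, pars, basis),
               hcam_marginal_loglik(dat, pars[1:3], basis),
               tolerance = 1e-8)
})

test_that("single-patient clusters are handled by the quadrature path", {
  set.seed(15)
  dat <- hospital_data(c("a", "b"), c(0, 1), matrix(rnorm(6), 2, 3),
                       cbind(1, rnorm(2)), c(0.1, 0.9))
  basis <- build_basis(dat$V, d = 1, q = 0)
  pars <- list(beta = c(0.2, -0.1, 0.3), gamma = c(0, 0),
               snp = snp_params(K = 1, a = 0, sigma = 1, angles = 0.4),
               theta = c(0.5, 0.2))
  expect_equal(zib_marginal_loglik(dat, pars, basis, n_quad = 21),
               trapezoid_marginal_loglik(dat, pars, basis),
               tolerance = 1e-6)
})

test_that("saturated limit: all-zero outcomes with certain survival give loglik near 0", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  dat <- hospital_data(rep(c("a", "b"), each = 5), rep(0, 10), X, NULL,
                       rep(c(0, 1), each = 5))
  basis <- build_basis(dat$V, d = 1, q = 0)
  pars <- list(beta = rep(0, 3), gamma = rep(0, 2),
               snp = snp_params(K = 0, a = -30, sigma = 0.01))
  expect_equal(hcam_marginal_loglik(dat, pars, basis), 0, tolerance = 1e-6)
})

test_that("K = 0 with a linear basis equals an independent classical GLMM likelihood", {
  set.seed(9)
  H <- 6; n_h <- 8
  idx <- rep(1:H, each = n_h)
  V <- seq(-1, 1, length.out = H)
  X <- matrix(rnorm(H * n_h * 2), ncol = 2)
  y <- rbinom(H * n_h, 1, plogis(0.3 * X[, 1] - 0.5 * X[, 2] + 0.4 * V[idx]))
  dat <- hospital_data(paste0("h", idx), y, X, NULL, V[idx])
  basis <- build_basis(dat$V, d = 1, q = 0)
  beta <- c(0.3, -0.5); gamma <- c(0.2, 0.5); a <- -0.1; sigma <- 0.7
  pars <- list(beta = beta, gamma = gamma,
               snp = snp_params(K = 0, a = a, sigma = sigma))
  ll <- hcam_marginal_loglik(dat, pars, basis, n_quad = 41)

  # independently coded random-intercept logistic likelihood (classical
  # GLMM): per-cluster Gauss-Legendre-free brute force on a fine grid
  offs <- drop(X %*% beta) + drop(basis$design[idx, ] %*% gamma)
  bg <- seq(-10, 10, length.out = 40001)
  ll_ref <- 0
  for (h in 1:H) {
    rows <- which(idx == h)
    vals <- vapply(bg, function(b) {
      p <- plogis(b + offs[rows])
      prod(ifelse(y[rows] == 1, p, 1 - p)) * dnorm(b, a, sigma)
    }, numeric(1))
    ll_ref <- ll_ref + log(sum((vals[-1] + vals[-40001]) / 2) * diff(bg[1:2]))
  }
  expect_equal(ll, ll_ref, tolerance = 1e-8)
})

test_that("Eq-form per-patient probability algebra: exponent terms equal rho*pi products", {
  set.seed(10)
  for (rep in 1:20) {
    tau <- runif(1, -4, 4); kappa <- runif(1, -4, 4)
    rho <- plogis(tau); pi_ <- plogis(kappa)
    # Y = 1 branch
    expect_equal(exp(tau + kappa - log1p(exp(tau)) - log1p(exp(kappa))),
                 rho * pi_, tolerance = 1e-12)
    # Y = 0 branch
    expect_equal(exp(log(1 + exp(tau) + exp(kappa)) -
                       log1p(exp(tau)) - log1p(exp(kappa))),
                 1 - rho * pi_, tolerance = 1e-12)
  }
})

marginal_ll_for <- function(f, data, basis, n_quad) {
  hcam_marginal_loglik(data, f$params, basis, n_quad = n_quad)
}

test_that("quadrature is stable in the node count and nested in K", {
  spec <- scenario_spec("A", H = 30, n_h = 15, dist = "asymmetric_mixture",
                        seed = 77)
  sim <- simulate_hospital_data(spec)
  fit <- fit_hcam(sim$data, K_grid = c(0, 1), n_quad = 15,
                  warn_no_event = FALSE)
  basis <- fit$basis
  for (f in fit$fits) {
    ll15 <- marginal_ll_for(f, sim$data, basis, 15)
    ll41 <- marginal_ll_for(f, sim$data, basis, 41)
    expect_equal(ll15, ll41, tolerance = 1e-4)
  }
  # nested warm start: flexible K never loses likelihood
  expect_gte(fit$fits$K1$loglik, fit$fits$K0$loglik - 1e-6)
  # information criteria bookkeeping
  for (f in fit$fits) {
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
    expect_equal(f$bic, -2 * f$loglik + f$n_params * log(sim$data$N))
  }
})

test_that("parameter recovery on simulated data and ZIB/HCAM nesting", {
  # one moderate replicate; deeper sweeps live in the acceptance tests
  spec <- scenario_spec("A", H = 60, n_h = 30, dist = "normal", seed = 5)
  sim <- simulate_hospital_data(spec)
  fit <- fit_hcam(sim$data, K_grid = 0, n_quad = 9, warn_no_event = FALSE)
  expect_true(fit$converged)
  m <- simulation_metrics(fit, sim$truth, sim$data)
  expect_lt(m$rd, 0.15)
  # the spline is centered over the sampled hospitals, so the identified
  # random-effect mean is sample_mean(b) + sample_mean(true f)
  expect_lt(abs(m$Eb_hat - mean(sim$truth$b) - mean(sim$truth$f)), 0.35)
  expect_equal(length(fit$b_modes), 60)
  expect_gt(cor(fit$b_modes, sim$truth$b), 0.3)
})

test_that("predicted probabilities obey the model algebra", {
  spec <- scenario_spec("A", H = 20, n_h = 10, seed = 3)
  sim <- simulate_hospital_data(spec)
  fit <- fit_hcam(sim$data, K_grid = 0, n_quad = 9, warn_no_event = FALSE)
  X0 <- matrix(0, 1, 3)
  # beta = 0, f and b as fitted: neutral covariates give logit^{-1}(b + f)
  fv <- evaluate_f(fit$basis, fit$params$gamma, sim$data$V)
  p <- predict_mortality(fit, X0, hospital = 4, data = sim$data)
  expect_equal(p, plogis(fit$b_modes[4] + fv[4]), tolerance = 1e-12)
  # monotone in a positive-coefficient covariate
  j <- which(fit$params$beta > 0)[1]
  Xa <- X0; Xb <- X0; Xb[, j] <- 1
  expect_gt(predict_mortality(fit, Xb, 4, sim$data),
            predict_mortality(fit, Xa, 4, sim$data))
  # ZIB product: rho = 0.5, pi = 0.5 => 0.25
  fitz <- fit
  fitz$model <- "zib"
  fitz$params$theta <- c(0, 0)
  eta0 <- -(fit$b_modes[4] + fv[4])   # X chosen so pi = 0.5
  Xpi <- matrix(c(eta0 / fit$params$beta[1], 0, 0), 1, 3)
  pz <- predict_mortality(fitz, Xpi, 4, sim$data, T_mat = cbind(1, 0))
  expect_equal(pz, 0.25, tolerance = 1e-10)
})

test_that("errors are descriptive", {
  dat <- toy_dataset()
  basis <- build_basis(dat$V, d = 1, q = 0)
  pars <- list(beta = c(Inf, 0, 0), gamma = c(0, 0),
               snp = snp_params())
  expect_error(hcam_marginal_loglik(dat, pars, basis), "hospital")
  expect_error(zib_marginal_loglik(toy_dataset(zib = FALSE),
                                   c(pars, list(theta = c(0, 0))), basis),
               "T covariates")
  expect_error(fit_hcam(toy_dataset(zib = FALSE), model = "zib"),
               "T covariates")
})
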