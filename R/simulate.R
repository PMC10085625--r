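#' Simulation harness for hospital compare models
#'
#' Generates clustered binary-outcome data from the generative designs used
#' to benchmark the models: a logistic model
#' Y ~ Bernoulli(logit^{-1}(b_h + f(V_h) + X' beta)) with
#' V_h ~ Uniform(-1, 1), X ~ N(0, I_3) and beta = (3, 0.5, -5); scenario A
#' varies the random-effect distribution over seven mean-zero unit-variance
#' shapes, scenario B varies the fixed-effect function f over four shapes
#' with a bimodal random effect, and the ZIB scenario adds a latent at-risk
#' status S ~ Bernoulli(logit^{-1}(theta X*)) with X* ~ N(1, 1.5^2), forcing
#' Y = 0 whenever S = 0.
#'
#' @name hcam-simulate
NULL

#' True fixed-effect functions used in the simulation designs
#'
#' f1(v) = 2v; f2(v) = (v - 0.5)^2 - 0.5833;
#' f3(v) = v cos^3(3v); f4(v) = exp(-2v) sin(6v) - 0.5748.
#' The constants center f2 and f4 to mean zero under V ~ Uniform(-1, 1)
#' (E[(V - 0.5)^2] = 1/3 + 1/4; the f4 constant is the closed-form average
#' of exp(-2v) sin(6v), see [fixed_effect_centering_constants()]).
#'
#' @param id Integer 1-4.
#' @param v Attribute values.
#' @return f(v).
#' @export
true_fixed_effect <- function(id, v) {
  id <- check_count(id, "id", min = 1L)
  if (id > 4L) stop("'id' must be 1, 2, 3 or 4")
  switch(id,
         2 * v,
         (v - 0.5)^2 - 0.5833,
         v * cos(3 * v)^3,
         exp(-2 * v) * sin(6 * v) - 0.5748)
}

#' Analytic centering constants of the simulation fixed effects
#'
#' Means under V ~ Uniform(-1, 1): for (v - 0.5)^2 the value is
#' 1/3 + 1/4 = 0.58333; for exp(-2v) sin(6v) the antiderivative
#' exp(-2v)(-2 sin 6v - 6 cos 6v)/40 gives 0.574914.
#'
#' @return Named vector `c(f2 = , f4 = )`.
#' @export
fixed_effect_centering_constants <- function() {
  Fv <- function(v) exp(-2 * v) * (-2 * sin(6 * v) - 6 * cos(6 * v)) / 40
  c(f2 = 1 / 3 + 1 / 4, f4 = (Fv(1) - Fv(-1)) / 2)
}

#' Standardization constants of the log-normal random-effect design
#'
#' The log-normal shape LogN(0, s) has unit variance when
#' (e^{s^2} - 1) e^{s^2} = 1, i.e. e^{s^2} is the golden ratio, giving
#' s = 0.693695; its mean e^{s^2/2} = 1.272020 is subtracted to center it.
#'
#' @return Named vector `c(sdlog = , meanshift = )`.
#' @export
lognormal_standardization <- function() {
  root <- stats::uniroot(function(s) (exp(s^2) - 1) * exp(s^2) - 1,
                         c(0.1, 2), tol = 1e-12)$root
  c(sdlog = root, meanshift = exp(root^2 / 2))
}

#' Random-effect distributions of the simulation designs
#'
#' Seven mean-zero unit-variance shapes plus the bimodal mixture
#' 0.7 N(-1.5, 0.7^2) + 0.3 N(2, 0.7^2) in raw (`"bimodal_raw"`, mean -0.45,
#' variance 3.0625) and standardized (`"bimodal_std"`) form.
#'
#' @param dist One of `"normal"`, `"uniform"`, `"exponential"`,
#'   `"lognormal"`, `"symmetric_mixture"`, `"asymmetric_mixture"`,
#'   `"discrete"`, `"bimodal_raw"`, `"bimodal_std"`, or an integer 1-7
#'   indexing the first seven in that order.
#' @param H Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `H`.
#' @export
sample_random_effect <- function(dist, H, seed = NULL) {
  H <- check_count(H, "H", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  nm <- c("normal", "uniform", "exponential", "lognormal",
          "symmetric_mixture", "asymmetric_mixture", "discrete")
  if (is.numeric(dist)) dist <- nm[check_count(dist, "dist", min = 1L)]
  dist <- match.arg(dist, c(nm, "bimodal_raw", "bimodal_std"))
  two_normals <- function(p1, m1, s1, m2, s2) {
    pick <- stats::runif(H) < p1
    stats::rnorm(H, ifelse(pick, m1, m2), ifelse(pick, s1, s2))
  }
  switch(dist,
    normal = stats::rnorm(H),
    uniform = stats::runif(H, -sqrt(3), sqrt(3)),
    exponential = stats::rexp(H) - 1,
    lognormal = {
      cst <- lognormal_standardization()
      stats::rlnorm(H, 0, cst[["sdlog"]]) - cst[["meanshift"]]
    },
    symmetric_mixture = {
      m <- sqrt(1 - 0.28^2)
      two_normals(0.5, -m, 0.28, m, 0.28)
    },
    asymmetric_mixture = two_normals(2 / 3, -2 / 3, 1 / 3, 4 / 3, 1 / 3),
    discrete = sample(c(-1, 1), H, replace = TRUE),
    bimodal_raw = two_normals(0.7, -1.5, 0.7, 2, 0.7),
    bimodal_std = (two_normals(0.7, -1.5, 0.7, 2, 0.7) + 0.45) / sqrt(3.0625)
  )
}

#' Specify a simulation scenario
#'
#' Defaults are the benchmark study conditions: H = 500 hospitals of n_h
#' patients each (50 for scenarios A/B, 100 for ZIB), beta = (3, 0.5, -5),
#' V ~ Uniform(-1, 1), X ~ N(0, I_3).  Scenario A fixes f = f4 and varies
#' the random-effect distribution; scenario B fixes the raw bimodal random
#' effect and varies f; the ZIB scenario uses f4 with the standardized
#' bimodal random effect and theta in {2, -2} controlling the average
#' proportion of positive events.
#'
#' @param scenario `"A"`, `"B"` or `"ZIB"`.
#' @param H,n_h Cluster count and cluster size (`n_h` defaults to 50 for
#'   A/B, 100 for ZIB).
#' @param dist Random-effect distribution (see [sample_random_effect()]);
#'   default `"normal"` for A, `"bimodal_raw"` for B, `"bimodal_std"` for
#'   ZIB.
#' @param f_id Fixed-effect function 1-4 (default 4 for A and ZIB, 1 for B).
#' @param beta Patient-effect coefficients.
#' @param theta ZIB status coefficient (scalar; default 2).
#' @param share_s_covariate If TRUE the N(1, 1.5^2) covariate driving the
#'   at-risk status replaces the first mortality covariate instead of being
#'   a separate fourth variable (default FALSE).
#' @param split Fraction of each cluster put in the training half when
#'   splitting (default 0.5).
#' @param seed Integer master seed; all components draw from named
#'   substreams derived from it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("A", "B", "ZIB"), H = 500L,
                          n_h = NULL, dist = NULL, f_id = NULL,
                          beta = c(3, 0.5, -5), theta = 2,
                          share_s_covariate = FALSE, split = 0.5,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(n_h)) n_h <- if (scenario == "ZIB") 100L else 50L
  if (is.null(dist)) {
    dist <- switch(scenario, A = "normal", B = "bimodal_raw",
                   ZIB = "bimodal_std")
  }
  if (is.null(f_id)) f_id <- if (scenario == "B") 1L else 4L
  structure(list(scenario = scenario, H = check_count(H, "H", 2L),
                 n_h = check_count(n_h, "n_h", 1L), dist = dist,
                 f_id = f_id, beta = as.numeric(beta), theta = theta,
                 share_s_covariate = isTRUE(share_s_covariate),
                 split = split, seed = check_count(seed, "seed", 0L)),
            class = "scenario_spec")
}

## deterministic named substreams below 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Generate a dataset from a scenario
#'
#' @param spec A [scenario_spec()].
#' @return A list: `data` (a [hospital_data()] object), `truth` (list with
#'   `b`, `f` at the hospital attributes, `beta`, `theta`, `S` statuses for
#'   ZIB, and the scenario spec) and, when a split is requested via
#'   [split_train_test()], train/test halves.
#' @export
simulate_hospital_data <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  H <- spec$H; n_h <- spec$n_h; N <- H * n_h
  b <- sample_random_effect(spec$dist, H, substream_seed(spec$seed, "b"))
  set.seed(substream_seed(spec$seed, "V"))
  V <- stats::runif(H, -1, 1)
  set.seed(substream_seed(spec$seed, "X"))
  X <- matrix(stats::rnorm(N * 3L), N, 3L,
              dimnames = list(NULL, paste0("x", 1:3)))
  idx <- rep(seq_len(H), each = n_h)
  fv <- true_fixed_effect(spec$f_id, V)
  T_mat <- NULL
  S <- rep(1, N)
  if (spec$scenario == "ZIB") {
    set.seed(substream_seed(spec$seed, "S"))
    xs <- stats::rnorm(N, 1, 1.5)
    if (spec$share_s_covariate) X[, 1L] <- xs
    ## theta = Inf is the "everyone at risk" limit (rho forced to 1)
    rho <- if (is.infinite(spec$theta) && spec$theta > 0) rep(1, N) else
      stats::plogis(spec$theta * xs)
    S <- stats::rbinom(N, 1L, rho)
    T_mat <- cbind(intercept = 1, xs = xs)
  }
  eta <- b[idx] + fv[idx] + drop(X %*% spec$beta)
  set.seed(substream_seed(spec$seed, "Y"))
  y <- S * stats::rbinom(N, 1L, stats::plogis(eta))
  data <- hospital_data(sprintf("h%04d", idx), y, X, T_mat, V[idx])
  list(data = data,
       truth = list(b = b, V = V, f = fv, beta = spec$beta,
                    theta = if (spec$scenario == "ZIB") spec$theta,
                    S = if (spec$scenario == "ZIB") S, spec = spec))
}

#' Split a dataset into train/test halves within each cluster
#'
#' @param data A [hospital_data()] object.
#' @param frac Training fraction per cluster (default 0.5, "equal size
#'   within each cluster").
#' @param seed Integer seed for the within-cluster shuffles.
#' @return List with `train` and `test` `hospital_data` objects and the
#'   logical row indicator `in_train`.
#' @export
split_train_test <- function(data, frac = 0.5, seed = 1L) {
  stopifnot(inherits(data, "hospital_data"))
  set.seed(check_count(seed, "seed", 0L))
  in_train <- logical(data$N)
  for (h in seq_len(data$H)) {
    rows <- which(data$hospital == h)
    ntr <- max(1L, floor(length(rows) * frac))
    in_train[sample(rows, ntr)] <- TRUE
  }
  list(train = subset_rows(data, in_train),
       test = subset_rows(data, !in_train),
       in_train = in_train)
}

## row subset keeping hospital identity/order; drops empty hospitals
subset_rows <- function(data, rows) {
  hospital_data(data$hospital_ids[data$hospital[rows]], data$y[rows],
                data$X[rows, , drop = FALSE],
                if (!is.null(data$T_mat)) data$T_mat[rows, , drop = FALSE],
                data$V[data$hospital][rows])
}

#' Evaluation metrics for a fitted model against simulation truth
#'
#' ISE = H^{-1} sum_h (fhat(V_h) - f(V_h))^2 over the build attributes;
#' RD = ||betahat - beta|| / ||beta||; AUC with a DeLong 95% CI on held-out
#' data; accuracy, F1 and PPV at a classification threshold equal to the
#' training-split observed event rate.
#'
#' @param fit An `hcam_fit` object.
#' @param truth The `truth` component of [simulate_hospital_data()].
#' @param train_data Data used for fitting (sets the threshold and aligns
#'   hospitals).
#' @param test_data Optional held-out [hospital_data()] for the
#'   classification metrics.
#' @return List with `ise`, `rd`, `Eb_hat`, `Varb_hat` and, when test data
#'   are given, `auc`, `auc_ci`, `accuracy`, `f1`, `ppv`, `threshold`.
#' @export
simulation_metrics <- function(fit, truth, train_data, test_data = NULL) {
  fhat <- evaluate_f(fit$basis, fit$params$gamma, truth$V)
  out <- list(
    ise = mean((fhat - truth$f)^2),
    rd = sqrt(sum((fit$params$beta - truth$beta)^2)) /
      sqrt(sum(truth$beta^2)),
    Eb_hat = fit$random_effect_mean,
    Varb_hat = fit$random_effect_variance
  )
  if (!is.null(test_data)) {
    p <- predict_mortality(fit, test_data$X, test_data$hospital, train_data,
                           T_mat = test_data$T_mat)
    out <- c(out, classification_metrics(test_data$y, p,
                                         threshold = mean(train_data$y)))
  }
  out
}

#' Binary classification metrics at a fixed threshold
#'
#' @param y Observed 0/1 labels.
#' @param scores Predicted probabilities or scores.
#' @param threshold Classification cutoff (canonically the training
#'   observed event rate).
#' @return List with `auc`, `auc_ci` (DeLong 95%), `accuracy`, `f1`, `ppv`,
#'   `threshold`.
#' @export
classification_metrics <- function(y, scores, threshold) {
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(ppv + rec > 0)) 2 * ppv * rec / (ppv + rec) else NA_real_
  list(auc = as.numeric(pROC::auc(roc)), auc_ci = ci[c(1L, 3L)],
       accuracy = mean(pred == y), f1 = f1, ppv = ppv,
       threshold = threshold)
}
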