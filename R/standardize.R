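#' Risk-standardized mortality rates and hospital ranking
#'
#' Given a fitted model, each hospital h gets: its observed rate OR_h; its
#' model-average rate P_h (mean predicted risk over its own patients); an
#' expected rate E_h (each of its patients evaluated at every hospital,
#' averaged uniformly or with weights w_H summing to 1); the indirectly
#' standardized rate P^IS_h = (P_h / E_h) x OR with OR the overall observed
#' rate; and the directly standardized rate P^DS_h = the hospital's average
#' predicted risk over the covariates of all N patients in the study.  For
#' zero-inflated fits every prediction is pi_H(X) * rho(T).
#'
#' @name hcam-standardize
NULL

#' Observed event rates
#'
#' @param data A [hospital_data()] object.
#' @return List with overall rate `OR` and per-hospital `OR_h`.
#' @export
observed_rates <- function(data) {
  stopifnot(inherits(data, "hospital_data"))
  list(OR = mean(data$y),
       OR_h = unname(drop(rowsum(data$y, data$hospital, reorder = TRUE))) /
         data$n_h)
}

## H x N matrix of p_H(X_hj): row = treating hospital, column = patient.
## ZIB: column j additionally multiplied by rho(T_j).
prediction_matrix <- function(fit, data) {
  fv <- evaluate_f(fit$basis, fit$params$gamma, data$V)
  eta_x <- drop(data$X %*% fit$params$beta)
  P <- stats::plogis(outer(fit$b_modes + fv, eta_x, `+`))
  if (fit$model == "zib") {
    if (is.null(data$T_mat)) stop("ZIB standardization requires T covariates")
    rho <- stats::plogis(drop(data$T_mat %*% fit$params$theta))
    P <- sweep(P, 2L, rho, `*`)
  }
  P
}

#' Model-average hospital risk P_h
#'
#' @param fit An `hcam_fit` with `b_modes`.
#' @param data The fitted [hospital_data()].
#' @return Numeric vector of length H.
#' @export
hospital_risk_P <- function(fit, data) {
  P <- prediction_matrix(fit, data)
  own <- P[cbind(data$hospital, seq_len(data$N))]
  unname(drop(rowsum(own, data$hospital, reorder = TRUE))) / data$n_h
}

#' Expected (benchmark) hospital risk E_h
#'
#' For each of hospital h's patients, the (weighted) average over all
#' hospitals of that patient's predicted risk, then averaged over the
#' hospital's patients.  Uniform weights give the plain form; weights
#' n_H / N give the volume-weighted form.
#'
#' @inheritParams hospital_risk_P
#' @param weights `"uniform"`, `"volume"` (n_H / N) or a numeric vector of
#'   length H summing to 1.
#' @return Numeric vector of length H.
#' @export
expected_risk_E <- function(fit, data, weights = "uniform") {
  w <- standardization_weights(weights, data)
  P <- prediction_matrix(fit, data)
  patient_expected <- drop(crossprod(P, w))        # sum_H w_H p_H(X_j)
  unname(drop(rowsum(patient_expected, data$hospital, reorder = TRUE))) /
    data$n_h
}

standardization_weights <- function(weights, data) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("uniform", "volume"))
    if (weights == "uniform") return(rep(1 / data$H, data$H))
    return(data$n_h / data$N)
  }
  w <- as.numeric(weights)
  if (length(w) != data$H) stop("'weights' must have length H")
  if (abs(sum(w) - 1) > 1e-8) stop("'weights' must sum to 1")
  w
}

#' Indirectly standardized rate
#'
#' P^IS_h = (P_h / E_h) x OR; the ratio form can exceed 1 and is reported
#' as-is.
#'
#' @param P_h,E_h Per-hospital risk and expected risk.
#' @param OR Overall observed rate.
#' @export
indirect_rate <- function(P_h, E_h, OR) (P_h / E_h) * OR

#' Directly standardized rate
#'
#' P^DS_h: hospital h's average predicted risk over the covariate rows of
#' every patient in the dataset (all N rows).
#'
#' @inheritParams hospital_risk_P
#' @export
direct_rate <- function(fit, data) {
  rowMeans(prediction_matrix(fit, data))
}

#' Ranks and quartiles from standardized rates
#'
#' Rank 1 = lowest rate = best; ties keep hospital (input) order.  Quartile
#' labels run 1 (best) to 4 (worst) by rank position, with group sizes
#' differing by at most one when H is not divisible by 4.
#'
#' @param rates Numeric vector of per-hospital rates.
#' @return List with integer `ranks` (a permutation of 1..H) and integer
#'   `quartiles`.
#' @export
rank_and_quartiles <- function(rates) {
  ranks <- rank(rates, ties.method = "first")
  list(ranks = as.integer(ranks),
       quartiles = as.integer(floor((ranks - 1L) * 4L / length(rates)) + 1L))
}

#' Standardized-rate table for a fitted model
#'
#' @inheritParams hospital_risk_P
#' @param weights Passed to [expected_risk_E()].
#' @param rank_on `"direct"` or `"indirect"`: which rate drives ranks and
#'   quartiles.
#' @return A `standardized_rates` data.frame: hospital_id, n_h, OR_h, P_h,
#'   E_h, P_IS, P_DS, rank, quartile.
#' @export
standardized_rates <- function(fit, data, weights = "uniform",
                               rank_on = c("direct", "indirect")) {
  rank_on <- match.arg(rank_on)
  obs <- observed_rates(data)
  P_h <- hospital_risk_P(fit, data)
  E_h <- expected_risk_E(fit, data, weights)
  P_IS <- indirect_rate(P_h, E_h, obs$OR)
  P_DS <- direct_rate(fit, data)
  rq <- rank_and_quartiles(if (rank_on == "direct") P_DS else P_IS)
  out <- data.frame(hospital_id = data$hospital_ids, n_h = data$n_h,
                    OR_h = obs$OR_h, P_h = P_h, E_h = E_h, P_IS = P_IS,
                    P_DS = P_DS, rank = rq$ranks, quartile = rq$quartiles,
                    row.names = NULL)
  attr(out, "OR") <- obs$OR
  attr(out, "rank_on") <- rank_on
  class(out) <- c("standardized_rates", "data.frame")
  out
}

#' @export
print.standardized_rates <- function(x, ...) {
  cat(sprintf(
    "Risk-standardized rates for %d hospitals (overall observed rate %.4f, ranked on %s)\n",
    nrow(x), attr(x, "OR"), attr(x, "rank_on")))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more hospitals\n")
  invisible(x)
}

#' Subsampling/bootstrap intervals for standardized rates
#'
#' Each replicate draws `m` patient rows (without replacement by default,
#' matching the resampling scheme of large ICU registry analyses; set
#' `replace = TRUE` for a classical bootstrap), recomputes the standardized
#' rates under the *fixed* fitted parameters, and reports percentile
#' intervals.  Hospitals absent from a replicate contribute nothing to it.
#'
#' @inheritParams hospital_risk_P
#' @param B Number of replicates (canonically 2000).
#' @param m Cases per replicate (canonically 2000); must be <= N.
#' @param level Interval level (default 0.95).
#' @param weights Passed to [expected_risk_E()] (recomputed per replicate).
#' @param statistic `"direct"` or `"indirect"`.
#' @param replace Sample with replacement? Default FALSE.
#' @param seed Integer seed.
#' @return Data frame: hospital_id, estimate, ci_low, ci_high, n_replicates
#'   (replicates in which the hospital appeared).
#' @export
bootstrap_ci <- function(fit, data, B = 2000L, m = 2000L, level = 0.95,
                         weights = "uniform",
                         statistic = c("direct", "indirect"),
                         replace = FALSE, seed = 1L) {
  statistic <- match.arg(statistic)
  B <- check_count(B, "B", min = 1L)
  m <- check_count(m, "m", min = 1L)
  if (!replace && m > data$N) stop("'m' must be <= N when resampling without replacement")
  set.seed(check_count(seed, "seed", 0L))
  ## fixed model quantities reused in every replicate
  fv <- evaluate_f(fit$basis, fit$params$gamma, data$V)
  hosp_eff <- fit$b_modes + fv
  eta_x <- drop(data$X %*% fit$params$beta)
  rho <- if (fit$model == "zib") {
    stats::plogis(drop(data$T_mat %*% fit$params$theta))
  } else {
    rep(1, data$N)
  }
  stat_mat <- matrix(NA_real_, B, data$H)
  for (rep_i in seq_len(B)) {
    rows <- sample.int(data$N, m, replace = replace)
    idx <- data$hospital[rows]
    P <- sweep(stats::plogis(outer(hosp_eff, eta_x[rows], `+`)), 2L,
               rho[rows], `*`)
    present <- sort(unique(idx))
    nh <- tabulate(idx, nbins = data$H)[present]
    if (statistic == "direct") {
      stat_mat[rep_i, ] <- rowMeans(P)
    } else {
      own <- P[cbind(idx, seq_along(rows))]
      P_h <- drop(rowsum(own, idx, reorder = TRUE)) / nh
      w <- standardization_weights(weights, data)
      pe <- drop(crossprod(P, w))
      E_h <- drop(rowsum(pe, idx, reorder = TRUE)) / nh
      stat_mat[rep_i, present] <- (P_h / E_h) * mean(data$y[rows])
    }
  }
  est <- if (statistic == "direct") direct_rate(fit, data) else {
    indirect_rate(hospital_risk_P(fit, data),
                  expected_risk_E(fit, data, weights),
                  mean(data$y))
  }
  alpha <- (1 - level) / 2
  qs <- apply(stat_mat, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  data.frame(hospital_id = data$hospital_ids, estimate = est,
             ci_low = qs[1L, ], ci_high = qs[2L, ],
             n_replicates = colSums(!is.na(stat_mat)), row.names = NULL)
}
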