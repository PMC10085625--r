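# Small deterministic fixtures built in code.

# two-hospital toy dataset with optional zero-inflation covariates
toy_dataset <- function(seed = 1, zib = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(12), 4, 3)
  T_mat <- if (zib) cbind(1, rnorm(4)) else NULL
  hospital_data(c("a", "a", "b", "b"), c(1, 0, 0, 1), X, T_mat,
                c(0.3, 0.3, -0.5, -0.5))
}

# dense trapezoid integration of the cluster-product marginal likelihood;
# independent of the adaptive-quadrature code path
trapezoid_marginal_loglik <- function(data, params, basis,
                                      lower = -8, upper = 8, n = 20001) {
  bg <- seq(lower, upper, length.out = n)
  offs <- drop(data$X %*% params$beta) +
    drop(basis$design[data$hospital, , drop = FALSE] %*% params$gamma)
  tau <- if (!is.null(params$theta)) drop(data$T_mat %*% params$theta)
  total <- 0
  for (h in seq_len(data$H)) {
    rows <- which(data$hospital == h)
    integrand <- vapply(bg, function(b) {
      k <- b + offs[rows]
      lp <- if (is.null(tau)) {
        sum(data$y[rows] * k - log1p(exp(k)))
      } else {
        t <- tau[rows]
        sum(ifelse(data$y[rows] == 1, t + k,
                   log(1 + exp(t) + exp(k))) -
              log1p(exp(t)) - log1p(exp(k)))
      }
      exp(lp) * snp_pdf(b, params$snp)
    }, numeric(1))
    total <- total +
      log(sum((integrand[-1] + integrand[-n]) / 2) * diff(bg[1:2]))
  }
  total
}

# naive Cox-de Boor recursion, independent of splines::splineDesign
cox_de_boor <- function(knots, u, d) {
  nb <- length(knots) - d - 1L
  B <- sapply(seq_len(length(knots) - 1L), function(i) {
    as.numeric(u >= knots[i] & u < knots[i + 1L])
  })
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
  for (deg in seq_len(d)) {
    Bnew <- matrix(0, length(u), ncol(B) - 1L)
    for (i in seq_len(ncol(Bnew))) {
      d1 <- knots[i + deg] - knots[i]
      d2 <- knots[i + deg + 1L] - knots[i + 1L]
      a1 <- if (d1 > 0) (u - knots[i]) / d1 else 0
      a2 <- if (d2 > 0) (knots[i + deg + 1L] - u) / d2 else 0
      Bnew[, i] <- a1 * B[, i] + a2 * B[, i + 1L]
    }
    B <- Bnew
  }
  B[, seq_len(nb), drop = FALSE]
}
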