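#' Save and load fitted models as JSON documents
#'
#' The document stores the model type, the spline basis specification
#' (degree, interior knots, knot vector, domain, centering offsets), all
#' parameter estimates (beta, gamma, SNP K/a/sigma/angles, theta),
#' empirical-Bayes modes, fit diagnostics and the K selection table, plus a
#' format version.  Parameters round-trip bit-identically (full double
#' precision).
#'
#' @param fit An `hcam_fit` object.
#' @param path Output path.
#' @return `path` invisibly (`save_model`); an `hcam_fit` (`load_model`).
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "hcam_fit"))
  doc <- list(
    format = "hcam-model", version = 1L,
    model = fit$model,
    basis = fit$basis[c("degree", "q", "knots", "domain", "knot_placement",
                        "centering_offsets")],
    params = list(beta = fit$params$beta, gamma = fit$params$gamma,
                  theta = fit$params$theta,
                  snp = fit$params$snp[c("K", "a", "sigma", "angles")]),
    b_modes = fit$b_modes,
    diagnostics = fit[c("loglik", "aic", "bic", "n_params", "n_quad",
                        "converged", "iterations", "random_effect_mean",
                        "random_effect_variance", "K")],
    K_table = fit$K_table
  )
  ## I(17) = 17 significant digits: doubles round-trip bit-identically
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hcam-model")) {
    stop(path, " is not an hcam model document")
  }
  if (doc$version > 1L) {
    stop("model document version ", doc$version,
         " is newer than this package supports (1)")
  }
  basis <- structure(
    list(degree = as.integer(doc$basis$degree), q = as.integer(doc$basis$q),
         knots = as.numeric(doc$basis$knots),
         domain = as.numeric(doc$basis$domain),
         knot_placement = doc$basis$knot_placement,
         centering_offsets = as.numeric(doc$basis$centering_offsets),
         design = NULL),
    class = "spline_basis")
  snp <- snp_params(K = as.integer(doc$params$snp$K), a = doc$params$snp$a,
                    sigma = doc$params$snp$sigma,
                    angles = as.numeric(doc$params$snp$angles))
  d <- doc$diagnostics
  structure(list(
    model = doc$model,
    params = list(beta = as.numeric(doc$params$beta),
                  gamma = as.numeric(doc$params$gamma),
                  snp = snp,
                  theta = if (!is.null(doc$params$theta))
                    as.numeric(doc$params$theta)),
    basis = basis, loglik = d$loglik, aic = d$aic, bic = d$bic,
    n_params = d$n_params, n_quad = as.integer(d$n_quad),
    converged = isTRUE(d$converged), iterations = d$iterations,
    random_effect_mean = d$random_effect_mean,
    random_effect_variance = d$random_effect_variance,
    K = as.integer(d$K), K_table = doc$K_table,
    b_modes = as.numeric(doc$b_modes)
  ), class = "hcam_fit")
}
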