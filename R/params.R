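#' Parameter set of the LUCID model
#'
#' Collects the full parameter vector Theta of the model: multinomial-logit
#' coefficients `beta` for the cluster-membership model X | G (K x (p+1),
#' intercept first; the row of the reference cluster 1 is fixed at zero),
#' cluster-specific omics means `mu` (K x m) and covariances `Sigma` (list
#' of K symmetric positive-definite m x m matrices), and cluster-specific
#' outcome means `gamma` and variances `sigma2` (length-K vectors).
#'
#' @param beta K x (p+1) matrix; first row all zero.
#' @param mu K x m matrix of cluster means.
#' @param Sigma list of K positive-definite m x m matrices.
#' @param gamma numeric length K.
#' @param sigma2 numeric length K, strictly positive.
#' @param cov_model covariance family tag, one of `"EII"`, `"VII"`,
#'   `"EEE"`, `"VVV"` (eigen-decomposition families: equal/varying volume,
#'   spherical/shared/full shape and orientation).
#' @return A `lucid_params` object.
#' @export
lucid_params <- function(beta, mu, Sigma, gamma, sigma2, cov_model = "VVV") {
  beta <- as.matrix(beta)
  mu <- as.matrix(mu)
  if (!is.list(Sigma)) Sigma <- list(as.matrix(Sigma))
  Sigma <- lapply(Sigma, as.matrix)
  gamma <- as.numeric(gamma)
  sigma2 <- as.numeric(sigma2)
  K <- nrow(mu)
  m <- ncol(mu)
  cov_model <- match.arg(cov_model, c("EII", "VII", "EEE", "VVV"))
  if (nrow(beta) != K) stop("beta must have K rows")
  if (length(Sigma) != K || length(gamma) != K || length(sigma2) != K)
    stop("Sigma, gamma, sigma2 must all have K components")
  if (max(abs(beta[1L, ])) > 1e-12)
    stop("reference-cluster row of beta must be zero")
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  for (j in seq_len(K)) {
    S <- Sigma[[j]]
    if (nrow(S) != m || ncol(S) != m) stop("Sigma dimensions must match mu")
    if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
      stop("Sigma[[", j, "]] is not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("Sigma[[", j, "]] is not positive definite")
  }
  structure(list(beta = beta, mu = mu, Sigma = Sigma, gamma = gamma,
                 sigma2 = sigma2, cov_model = cov_model, K = K, m = m,
                 p = ncol(beta) - 1L),
            class = "lucid_params")
}

#' @export
print.lucid_params <- function(x, ...) {
  cat(sprintf("lucid_params: K = %d clusters, p = %d exposures, m = %d omics (%s covariance)\n",
              x$K, x$p, x$m, x$cov_model))
  cat("  gamma:", format(x$gamma, digits = 4), "\n")
  invisible(x)
}

# permute cluster labels; softmax is shift-invariant so beta is re-referenced
# against the new cluster 1 row
permute_params <- function(params, perm) {
  beta <- params$beta[perm, , drop = FALSE]
  beta <- sweep(beta, 2, beta[1L, ])
  lucid_params(beta = beta,
               mu = params$mu[perm, , drop = FALSE],
               Sigma = params$Sigma[perm],
               gamma = params$gamma[perm],
               sigma2 = params$sigma2[perm],
               cov_model = params$cov_model)
}
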