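# Per-iteration computations of the EM algorithm: cluster-membership
# probabilities, responsibilities under complete and list-wise-missing
# rows, closed-form M-steps, and the within-loop imputation (I-step) for
# sporadically missing omics cells.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix
row_logsumexp <- function(X) {
  m <- X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  out <- m + log(rowSums(exp(X - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# ridge applied to a cluster covariance when it is numerically singular;
# scaled to the mean diagonal so it is unit-free
ridge_sigma <- function(S, eps = 1e-6) {
  S + diag(eps * mean(diag(S)), nrow(S))
}

# Cholesky with lazy regularisation: factorise the matrix as given and
# only add an (escalating) ridge when the factorisation fails, so
# well-conditioned inputs are handled in exact arithmetic
safe_chol <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  eps <- 1e-6
  while (is.null(ch) && eps <= 1e-2) {
    ch <- tryCatch(chol(ridge_sigma(S, eps)), error = function(e) NULL)
    eps <- eps * 100
  }
  if (is.null(ch)) stop("covariance matrix is singular")
  ch
}

# inverse via the regularised Cholesky
safe_solve <- function(S) {
  chol2inv(safe_chol(S))
}

# log N(z | mu, Sigma) for every row of Z, via Cholesky
dmvnorm_log <- function(Z, mu, Sigma) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  ch <- safe_chol(Sigma)
  dev <- sweep(Z, 2, mu)
  u <- backsolve(ch, t(dev), transpose = TRUE)  # solves t(ch) %*% u = t(dev)
  quad <- colSums(u^2)
  -0.5 * (m * log(2 * pi) + quad) - sum(log(diag(ch)))
}

#' Cluster-membership probabilities from the exposure model
#'
#' Evaluates the multinomial-logit (softmax) probabilities S(X = j | G;
#' beta) for every observation, computed through log-sum-exp so that large
#' linear predictors do not overflow.
#'
#' @param G numeric n x p exposure matrix.
#' @param beta K x (p+1) coefficient matrix, intercept column first,
#'   reference row (cluster 1) zero.
#' @param log if `TRUE`, return log-probabilities.
#' @return n x K matrix whose rows sum to 1 (or to 0 on the log scale).
#' @export
softmax_probs <- function(G, beta, log = FALSE) {
  G <- as.matrix(G)
  beta <- as.matrix(beta)
  if (ncol(beta) != ncol(G) + 1L)
    stop("beta must have p+1 columns (intercept first)")
  if (max(abs(beta[1L, ])) > 1e-12)
    stop("reference-cluster row of beta must be zero")
  eta <- cbind(1, G) %*% t(beta)          # n x K linear predictors
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  lp <- eta - row_logsumexp(eta)
  if (log) lp else exp(lp)
}

# log joint density components shared by the responsibility computations:
# returns n x K matrix of log S + optional log phi(Z) + optional log phi(Y)
log_component_matrix <- function(G, Z, Y, params, use_z = TRUE, use_y = TRUE) {
  K <- params$K
  lp <- softmax_probs(G, params$beta, log = TRUE)
  if (use_y) {
    for (j in seq_len(K))
      lp[, j] <- lp[, j] + stats::dnorm(Y, params$gamma[j],
                                        sqrt(params$sigma2[j]), log = TRUE)
  }
  if (use_z) {
    for (j in seq_len(K))
      lp[, j] <- lp[, j] + dmvnorm_log(Z, params$mu[j, ], params$Sigma[[j]])
  }
  lp
}

#' Responsibilities for rows with a complete (or currently imputed) omics row
#'
#' Posterior inclusion probabilities r_ij that observation i belongs to
#' cluster j, combining the exposure, omics and outcome likelihood terms:
#' r_ij is proportional to S(X=j | G_i) * phi(Z_i | mu_j, Sigma_j) *
#' phi(Y_i | gamma_j, sigma2_j), normalised over j in log space.
#'
#' @param G,Z,Y data components; `Z` rows must carry no unresolved missing
#'   cells (sporadically missing rows use their current imputations).
#' @param params a [lucid_params] object.
#' @return n x K responsibility matrix; rows sum to 1.
#' @export
responsibilities_complete <- function(G, Z, Y, params) {
  if (anyNA(Z)) stop("Z rows must be complete or currently imputed")
  lp <- log_component_matrix(G, Z, Y, params)
  r <- exp(lp - row_logsumexp(lp))
  r / rowSums(r)
}

#' Responsibilities for rows whose omics row is entirely missing
#'
#' For list-wise missing rows the omics density term drops out of the
#' likelihood partition, so r_ij is proportional to
#' S(X=j | G_i) * phi(Y_i | gamma_j, sigma2_j) only.
#'
#' @inheritParams responsibilities_complete
#' @return n x K responsibility matrix; rows sum to 1.
#' @export
responsibilities_listwise <- function(G, Y, params) {
  lp <- log_component_matrix(G, Z = NULL, Y, params, use_z = FALSE)
  r <- exp(lp - row_logsumexp(lp))
  r / rowSums(r)
}

# weighted multinomial-logit negative log-likelihood and gradient over the
# free rows of beta (clusters 2..K); theta is the vectorised free block
beta_negll <- function(theta, X, r, K) {
  pp1 <- ncol(X)
  beta <- rbind(0, matrix(theta, nrow = K - 1L, ncol = pp1))
  eta <- X %*% t(beta)
  lp <- eta - row_logsumexp(eta)
  -sum(r * lp)
}

beta_negll_grad <- function(theta, X, r, K) {
  pp1 <- ncol(X)
  beta <- rbind(0, matrix(theta, nrow = K - 1L, ncol = pp1))
  eta <- X %*% t(beta)
  P <- exp(eta - row_logsumexp(eta))
  w <- rowSums(r)
  resid <- P * w - r                       # n x K
  g <- t(resid[, -1L, drop = FALSE]) %*% X # (K-1) x (p+1)
  as.vector(g)
}

#' M-step update of the exposure-to-cluster coefficients
#'
#' Maximises the responsibility-weighted multinomial log-likelihood
#' sum_ij r_ij log S(X_i = j | G_i; beta). No closed form exists; the
#' problem is concave, so the update runs damped Newton-Raphson with the
#' analytic gradient and Hessian, warm-started from the current
#' coefficients, to a gradient-norm tolerance.
#'
#' @param G n x p exposure matrix.
#' @param r n x K responsibility matrix (all rows, including list-wise
#'   missing ones with their partitioned responsibilities).
#' @param beta_init optional warm start (K x (p+1)).
#' @param tol absolute gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return K x (p+1) coefficient matrix with zero reference row and
#'   attribute `converged`.
#' @export
m_step_beta <- function(G, r, beta_init = NULL, tol = 1e-6, max_iter = 100L) {
  G <- as.matrix(G)
  r <- as.matrix(r)
  K <- ncol(r)
  X <- cbind(1, G)
  pp1 <- ncol(X)
  if (K == 1L) {
    beta <- matrix(0, 1L, pp1)
    attr(beta, "converged") <- TRUE
    return(beta)
  }
  free <- K - 1L
  theta <- if (is.null(beta_init)) rep(0, free * pp1) else
    as.vector(beta_init[-1L, , drop = FALSE])
  w <- rowSums(r)
  gtol <- tol
  converged <- FALSE
  nll <- beta_negll(theta, X, r, K)
  for (it in seq_len(max_iter)) {
    beta <- rbind(0, matrix(theta, nrow = free, ncol = pp1))
    eta <- X %*% t(beta)
    P <- exp(eta - row_logsumexp(eta))
    g <- as.vector(t((P * w - r)[, -1L, drop = FALSE]) %*% X)
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    # Hessian of the negative log-likelihood over the free classes
    H <- matrix(0, free * pp1, free * pp1)
    for (u in seq_len(free)) {
      for (v in u:free) {
        s <- P[, u + 1L] * ((u == v) - P[, v + 1L]) * w
        M <- crossprod(X, X * s)
        ri <- seq(u, by = free, length.out = pp1)
        ci <- seq(v, by = free, length.out = pp1)
        H[ri, ci] <- M
        if (u != v) H[ci, ri] <- t(M)
      }
    }
    delta <- tryCatch(solve(H + diag(1e-10, nrow(H)), g),
                      error = function(e) g / max(1, sum(w)))
    # damped step: halve until the objective does not increase
    step <- 1
    repeat {
      theta_new <- theta - step * delta
      nll_new <- beta_negll(theta_new, X, r, K)
      if (is.finite(nll_new) && nll_new <= nll + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { theta_new <- theta; nll_new <- nll; break }
    }
    theta <- theta_new
    nll <- nll_new
  }
  if (!converged) {
    g <- beta_negll_grad(theta, X, r, K)
    converged <- max(abs(g)) < gtol
    if (!converged)
      warning("beta update did not reach gradient tolerance (max |grad| = ",
              signif(max(abs(g)), 3), "); returning last iterate")
  }
  beta <- rbind(0, matrix(theta, nrow = free, ncol = pp1))
  attr(beta, "converged") <- converged
  beta
}

#' M-step update of the cluster Gaussian parameters for the omics layer
#'
#' Weighted-moment updates: mu_j is the responsibility-weighted mean of the
#' omics rows; the covariance update depends on the eigen-decomposition
#' family. `VVV` uses the unconstrained weighted scatter per cluster,
#' `EEE` pools one full covariance, `VII` fits a spherical covariance per
#' cluster and `EII` one shared spherical covariance. Only rows whose
#' omics values are observed (or currently imputed) participate; list-wise
#' missing rows carry no information about mu or Sigma.
#'
#' @param Z n x m omics rows (complete or imputed; no `NA`).
#' @param r matching n x K responsibilities.
#' @param cov_model one of `"EII"`, `"VII"`, `"EEE"`, `"VVV"`.
#' @param weight_floor minimum effective cluster weight, as a fraction of
#'   n, below which the cluster is declared degenerate.
#' @return list with `mu` (K x m) and `Sigma` (list of K matrices).
#' @export
m_step_gaussian_z <- function(Z, r, cov_model = "VVV", weight_floor = 1e-6) {
  Z <- as.matrix(Z)
  r <- as.matrix(r)
  if (anyNA(Z)) stop("Z rows must be complete or imputed in the M-step")
  cov_model <- match.arg(cov_model, c("EII", "VII", "EEE", "VVV"))
  n <- nrow(Z); m <- ncol(Z); K <- ncol(r)
  nk <- colSums(r)
  if (any(nk < weight_floor * n))
    stop("degenerate cluster: effective weight below threshold (cluster ",
         which.min(nk), ")")
  mu <- t(r) %*% Z / nk
  W <- vector("list", K)               # weighted scatter matrices
  for (j in seq_len(K)) {
    dev <- sweep(Z, 2, mu[j, ])
    W[[j]] <- crossprod(dev * r[, j], dev)
  }
  N <- sum(nk)
  Sigma <- switch(cov_model,
    VVV = lapply(seq_len(K), function(j) W[[j]] / nk[j]),
    EEE = {
      S <- Reduce(`+`, W) / N
      rep(list(S), K)
    },
    VII = lapply(seq_len(K), function(j)
      diag(sum(diag(W[[j]])) / (nk[j] * m), m)),
    EII = {
      lam <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (N * m)
      rep(list(diag(lam, m)), K)
    })
  Sigma <- lapply(Sigma, function(S) ensure_pd((S + t(S)) / 2))
  list(mu = mu, Sigma = Sigma)
}

# lift a (numerically) rank-deficient scatter matrix to positive definite;
# leaves well-conditioned matrices untouched so closed-form arithmetic is
# exact in the regular case
ensure_pd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- 1e-8 * max(mean(diag(S)), 1e-8)
  if (min(ev) < floor_ev)
    S <- S + diag(floor_ev - min(ev), nrow(S))
  S
}

#' M-step update of the outcome model
#'
#' Cluster-specific weighted mean and maximum-likelihood variance of the
#' outcome; every row contributes, including list-wise missing ones (their
#' responsibilities come from the partitioned likelihood).
#'
#' @param Y outcome vector.
#' @param r n x K responsibilities.
#' @param sigma2_floor lower clip for the variances; hitting it raises a
#'   warning.
#' @return list with `gamma` and `sigma2`, each length K.
#' @export
m_step_outcome <- function(Y, r, sigma2_floor = 1e-8) {
  r <- as.matrix(r)
  nk <- colSums(r)
  gamma <- as.vector(t(r) %*% Y / nk)
  dev2 <- outer(Y, gamma, `-`)^2
  sigma2 <- colSums(r * dev2) / nk
  if (any(sigma2 < sigma2_floor)) {
    warning("outcome variance clipped to floor in cluster(s) ",
            paste(which(sigma2 < sigma2_floor), collapse = ", "))
    sigma2 <- pmax(sigma2, sigma2_floor)
  }
  list(gamma = gamma, sigma2 = sigma2)
}

#' I-step: update the missing cells of one sporadically missing omics row
#'
#' Solves the within-iteration imputation for a row whose omics vector
#' splits into an observed block `a` and a missing block `b`. Writing
#' P_j = Sigma_j^{-1} and partitioning the precision matrix (after
#' inversion) into blocks P_j^{aa}, P_j^{ab}, P_j^{ba}, P_j^{bb} aligned
#' with the row's observed/missing split, the update is
#'
#'   Z_b = \[ sum_j w_j P_j^{bb} \]^{-1} sum_j w_j ( P_j^{ba} mu_a +
#'            P_j^{bb} mu_b - P_j^{ba} Z_a )
#'
#' The default weights `w_j = r_ij` make this the exact maximiser of the
#' Q-function's omics term in the missing coordinates, which preserves the
#' EM ascent property of the surrounding loop. The alternative
#' `"density_scaled"` weighting multiplies each responsibility by
#' phi(Z_i^(t) | mu_j, Sigma_j) evaluated at the previous iterate's
#' imputed row; both weightings are normalised over j in log space (the
#' solution is invariant to joint rescaling, and normalising prevents
#' underflow). With K = 1 either choice reduces to the Gaussian
#' conditional mean mu_b + Sigma_ba Sigma_aa^{-1} (Z_a - mu_a).
#'
#' @param z_current length-m numeric row holding observed values and the
#'   previous iteration's imputations in the missing positions.
#' @param miss logical length-m vector; `TRUE` marks the missing block.
#' @param r_row length-K responsibilities of this row.
#' @param params a [lucid_params] object.
#' @param weighting `"responsibility"` (default) or `"density_scaled"`.
#' @return the row with the missing block replaced by its update.
#' @export
i_step_impute_row <- function(z_current, miss, r_row, params,
                              weighting = c("responsibility",
                                            "density_scaled")) {
  weighting <- match.arg(weighting)
  if (!any(miss)) return(z_current)       # no missing block: no-op
  if (all(miss)) stop("row is fully missing; handled by the likelihood partition")
  K <- params$K
  logw <- log(pmax(r_row, 1e-300))
  if (weighting == "density_scaled")
    for (j in seq_len(K))
      logw[j] <- logw[j] + dmvnorm_log(matrix(z_current, 1L),
                                       params$mu[j, ], params$Sigma[[j]])
  P_list <- lapply(params$Sigma, safe_solve)
  impute_row_core(z_current, miss, logw, params$mu, P_list,
                  which.max(r_row))
}

# shared solver: weights supplied on the log scale, precisions precomputed
impute_row_core <- function(z, miss, logw, mu, P_list, fallback_j) {
  K <- length(P_list)
  if (all(!is.finite(logw))) {
    # underflow of every weight: fall back to the dominant cluster
    logw <- rep(-Inf, K)
    logw[fallback_j] <- 0
  }
  w <- exp(logw - logsumexp(logw))
  a <- which(!miss); b <- which(miss)
  nb <- length(b)
  A <- matrix(0, nb, nb)
  rhs <- numeric(nb)
  for (j in seq_len(K)) {
    if (w[j] == 0) next
    P <- P_list[[j]]
    Pbb <- P[b, b, drop = FALSE]
    Pba <- P[b, a, drop = FALSE]
    A <- A + w[j] * Pbb
    rhs <- rhs + w[j] * (Pba %*% mu[j, a] + Pbb %*% mu[j, b] - Pba %*% z[a])
  }
  z[b] <- as.vector(solve(A, rhs))
  z
}

# apply the I-step to every sporadically missing row; precisions and (for
# the density-scaled weighting) log-densities are computed once per call
i_step <- function(Z_current, mask, ib, r, params,
                   weighting = "responsibility") {
  if (!length(ib)) return(Z_current)
  K <- params$K
  P_list <- lapply(params$Sigma, safe_solve)
  logw <- log(pmax(r[ib, , drop = FALSE], 1e-300))
  if (weighting == "density_scaled") {
    for (j in seq_len(K))
      logw[, j] <- logw[, j] + dmvnorm_log(Z_current[ib, , drop = FALSE],
                                           params$mu[j, ], params$Sigma[[j]])
  }
  for (t in seq_along(ib)) {
    i <- ib[t]
    Z_current[i, ] <- impute_row_core(Z_current[i, ], mask[i, ], logw[t, ],
                                      params$mu, P_list,
                                      which.max(r[i, ]))
  }
  Z_current
}

#' Partitioned observed-data log-likelihood
#'
#' Evaluates the log-likelihood of the model under the missingness
#' partition: rows with complete (or imputed) omics contribute
#' log sum_j S * phi(Z) * phi(Y); list-wise missing rows contribute
#' log sum_j S * phi(Y) with the omics density dropped. All mixture sums
#' use log-sum-exp.
#'
#' @param G,Y data components.
#' @param Z_imputed n x m omics matrix with sporadic cells imputed;
#'   list-wise missing rows may remain `NA` (they are never touched).
#' @param partition a [classify_missing_pattern] result.
#' @param params a [lucid_params] object.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(G, Z_imputed, Y, partition, params) {
  iab <- c(partition$ia, partition$ib)
  ll <- 0
  if (length(iab)) {
    lp <- log_component_matrix(G[iab, , drop = FALSE],
                               Z_imputed[iab, , drop = FALSE],
                               Y[iab], params)
    ll <- ll + sum(row_logsumexp(lp))
  }
  if (partition$n_c) {
    ic <- partition$ic
    lp <- log_component_matrix(G[ic, , drop = FALSE], NULL, Y[ic], params,
                               use_z = FALSE)
    ll <- ll + sum(row_logsumexp(lp))
  }
  if (!is.finite(ll))
    stop("non-finite log-likelihood; check for degenerate clusters or ",
         "extreme imputed values")
  ll
}
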