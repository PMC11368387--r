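# Independent reference implementations used as oracles. They follow the
# model definitions by naive direct arithmetic (plain exponentials and
# explicit sums, no log-space tricks, no code shared with the package) and
# are only ever run on small well-scaled fixtures.

naive_softmax <- function(G, beta) {
  X <- cbind(1, as.matrix(G))
  E <- exp(X %*% t(beta))
  E / rowSums(E)
}

naive_mvn_density <- function(z, mu, Sigma) {
  m <- length(mu)
  d <- z - mu
  as.numeric(exp(-0.5 * t(d) %*% solve(Sigma) %*% d) /
               sqrt((2 * pi)^m * det(Sigma)))
}

# responsibilities by direct Bayes-rule arithmetic, one row at a time
naive_responsibilities <- function(G, Z, Y, params, use_z = TRUE) {
  n <- nrow(as.matrix(G)); K <- params$K
  S <- naive_softmax(G, params$beta)
  r <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (j in seq_len(K)) {
      num <- S[i, j] *
        dnorm(Y[i], params$gamma[j], sqrt(params$sigma2[j]))
      if (use_z)
        num <- num * naive_mvn_density(as.matrix(Z)[i, ], params$mu[j, ],
                                       params$Sigma[[j]])
      r[i, j] <- num
    }
    r[i, ] <- r[i, ] / sum(r[i, ])
  }
  r
}

# weighted Gaussian moments with explicit loops (unconstrained family)
naive_gaussian_mstep <- function(Z, r) {
  Z <- as.matrix(Z); K <- ncol(r); m <- ncol(Z)
  mu <- matrix(0, K, m)
  Sigma <- vector("list", K)
  for (j in seq_len(K)) {
    nk <- sum(r[, j])
    mu[j, ] <- colSums(Z * r[, j]) / nk
    S <- matrix(0, m, m)
    for (i in seq_len(nrow(Z))) {
      d <- Z[i, ] - mu[j, ]
      S <- S + r[i, j] * (d %o% d)
    }
    Sigma[[j]] <- S / nk
  }
  list(mu = mu, Sigma = Sigma)
}

naive_outcome_mstep <- function(Y, r) {
  K <- ncol(r)
  gamma <- numeric(K); sigma2 <- numeric(K)
  for (j in seq_len(K)) {
    nk <- sum(r[, j])
    gamma[j] <- sum(r[, j] * Y) / nk
    sigma2[j] <- sum(r[, j] * (Y - gamma[j])^2) / nk
  }
  list(gamma = gamma, sigma2 = sigma2)
}

# weighted two-class logit via IRLS (glm with fractional responses); exact
# score equations of the weighted multinomial likelihood at K = 2
oracle_beta_k2 <- function(G, r) {
  fit <- suppressWarnings(
    glm(r[, 2] ~ as.matrix(G), family = quasibinomial(),
        control = glm.control(epsilon = 1e-14, maxit = 200)))
  rbind(0, coef(fit))
}

# direct (un-partitioned) mixture log-likelihood for complete data
naive_complete_loglik <- function(G, Z, Y, params) {
  n <- nrow(as.matrix(G)); K <- params$K
  S <- naive_softmax(G, params$beta)
  ll <- 0
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(K))
      tot <- tot + S[i, j] *
        naive_mvn_density(as.matrix(Z)[i, ], params$mu[j, ], params$Sigma[[j]]) *
        dnorm(Y[i], params$gamma[j], sqrt(params$sigma2[j]))
    ll <- ll + log(tot)
  }
  ll
}

# multivariate-normal conditional mean of the missing block given the
# observed block, by the covariance (not precision) formula
conditional_mean <- function(z_obs, obs_idx, miss_idx, mu, Sigma) {
  mu[miss_idx] +
    Sigma[miss_idx, obs_idx, drop = FALSE] %*%
    solve(Sigma[obs_idx, obs_idx, drop = FALSE]) %*%
    (z_obs - mu[obs_idx])
}

# AUC by exhaustive pair counting with half credit for ties
brute_force_auc <- function(score, pos) {
  s1 <- score[pos]; s0 <- score[!pos]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
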