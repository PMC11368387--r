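test_that("softmax probabilities match direct evaluation and edge cases", {
  G <- withr::with_seed(1, matrix(rnorm(30), 10, 3))
  # all-zero coefficients: uniform
  expect_equal(softmax_probs(G, matrix(0, 3, 4)),
               matrix(1 / 3, 10, 3), tolerance = 1e-12)
  # known odds: exp(log 2) = 2
  S <- softmax_probs(matrix(1, 1, 1), rbind(c(0, 0), c(0, log(2))))
  expect_equal(as.vector(S), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # random coefficients against naive exponentiation
  beta <- withr::with_seed(2, rbind(0, matrix(rnorm(8, sd = 0.5), 2, 4)))
  expect_equal(softmax_probs(G, beta), naive_softmax(G, beta),
               tolerance = 1e-10)
  expect_true(all(abs(rowSums(softmax_probs(G, beta)) - 1) < 1e-10))
})

test_that("softmax rejects invalid coefficient matrices", {
  G <- matrix(0, 2, 2)
  expect_error(softmax_probs(G, matrix(1, 2, 3)), "reference")
  expect_error(softmax_probs(G, matrix(0, 2, 2)), "p\\+1")
})

test_that("responsibilities agree with Bayes-rule arithmetic", {
  params <- scalar_params()
  G <- matrix(c(-0.3, 0.8, 1.2), 3, 1)
  Z <- matrix(c(0.5, -1.2, 2.0), 3, 1)
  Y <- c(0.1, -0.4, 1.3)
  r <- responsibilities_complete(G, Z, Y, params)
  expect_equal(r, naive_responsibilities(G, Z, Y, params), tolerance = 1e-8)
  expect_equal(rowSums(r), rep(1, 3), tolerance = 1e-10)

  rl <- responsibilities_listwise(G, Y, params)
  expect_equal(rl, naive_responsibilities(G, NULL, Y, params, use_z = FALSE),
               tolerance = 1e-8)
})

test_that("responsibility degenerate cases", {
  # single cluster: probability one
  p1 <- lucid_params(beta = matrix(0, 1, 2), mu = matrix(0, 1, 1),
                     Sigma = list(matrix(1)), gamma = 0, sigma2 = 1)
  r <- responsibilities_complete(matrix(0, 4, 1), matrix(0, 4, 1),
                                 rep(0, 4), p1)
  expect_equal(as.vector(r), rep(1, 4))
  # indistinguishable clusters: uniform responsibilities
  p2 <- lucid_params(beta = matrix(0, 3, 2),
                     mu = matrix(0, 3, 1), Sigma = rep(list(matrix(1)), 3),
                     gamma = rep(0, 3), sigma2 = rep(1, 3))
  r2 <- responsibilities_complete(matrix(rnorm(4), 4, 1),
                                  matrix(rnorm(4), 4, 1), rnorm(4), p2)
  expect_equal(r2, matrix(1 / 3, 4, 3), tolerance = 1e-12)
  # listwise responsibilities reduce to softmax when the outcome model is
  # identical across clusters
  p3 <- scalar_params()
  p3$gamma <- c(0.2, 0.2); p3$sigma2 <- c(1, 1)
  G <- matrix(rnorm(5), 5, 1)
  expect_equal(responsibilities_listwise(G, rnorm(5), p3),
               softmax_probs(G, p3$beta), tolerance = 1e-10)
})

test_that("beta M-step solves the weighted multinomial problem", {
  # intercept-only closed form: logit of the mean responsibility
  r <- cbind(rep(0.75, 40), rep(0.25, 40))
  G0 <- matrix(0, 40, 1)
  b <- m_step_beta(G0, r)
  expect_equal(b[2, 1], log(0.25 / 0.75), tolerance = 1e-6)
  # uninformative responsibilities: zero coefficients
  G <- withr::with_seed(5, matrix(rnorm(120), 60, 2))
  b0 <- m_step_beta(G, matrix(1 / 3, 60, 3))
  expect_equal(max(abs(b0)), 0, tolerance = 1e-6)
  # K = 2 against IRLS on fractional responses (independent route)
  rr <- random_resp(80, 2, seed = 6)
  G2 <- withr::with_seed(7, matrix(rnorm(240), 80, 3))
  b2 <- m_step_beta(G2, rr)
  expect_equal(unname(b2), unname(oracle_beta_k2(G2, rr)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # hard labels, non-separating design
  lab <- withr::with_seed(8, sample(1:2, 80, replace = TRUE))
  rh <- cbind(lab == 1, lab == 2) * 1
  bh <- m_step_beta(G2, rh)
  expect_equal(unname(bh), unname(oracle_beta_k2(G2, rh)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("Gaussian M-step reduces to sample moments under hard assignment", {
  Z <- withr::with_seed(9, matrix(rnorm(60), 20, 3))
  r <- cbind(rep(1, 20))
  gz <- m_step_gaussian_z(Z, r, "VVV")
  expect_equal(as.vector(gz$mu), colMeans(Z), tolerance = 1e-12)
  # maximum-likelihood covariance: denominator n, not n-1
  expect_equal(gz$Sigma[[1]], cov(Z) * 19 / 20, tolerance = 1e-12)
})

test_that("Gaussian M-step matches the naive weighted-moment oracle and mclust", {
  skip_if_not_installed("mclust")
  Z <- withr::with_seed(10, matrix(rnorm(100), 25, 4))
  r <- random_resp(25, 2, seed = 11)
  naive <- naive_gaussian_mstep(Z, r)
  for (fam in c("EII", "VII", "EEE", "VVV")) {
    got <- m_step_gaussian_z(Z, r, fam)
    expect_equal(got$mu, naive$mu, tolerance = 1e-10)
    ms <- getExportedValue("mclust", paste0("mstep", fam))(data = Z, z = r)
    expect_equal(got$mu, t(ms$parameters$mean), tolerance = 1e-8,
                 ignore_attr = TRUE)
    sig <- ms$parameters$variance$sigma
    for (j in 1:2)
      expect_equal(got$Sigma[[j]], sig[, , j], tolerance = 1e-8,
                   ignore_attr = TRUE)
  }
  # VVV equals the naive unconstrained scatter
  got <- m_step_gaussian_z(Z, r, "VVV")
  for (j in 1:2) expect_equal(got$Sigma[[j]], naive$Sigma[[j]],
                              tolerance = 1e-10)
  # EII: one shared spherical volume from total weighted squared deviation
  lam <- sum(vapply(1:2, function(j)
    sum(r[, j] * rowSums(sweep(Z, 2, naive$mu[j, ])^2)), 0)) / (25 * 4)
  expect_equal(m_step_gaussian_z(Z, r, "EII")$Sigma[[1]], diag(lam, 4),
               tolerance = 1e-10)
})

test_that("each Gaussian M-step weakly increases its Q-function term", {
  Z <- withr::with_seed(12, matrix(rnorm(80), 20, 4))
  r <- random_resp(20, 2, seed = 13)
  qterm <- function(mu, Sigma) {
    tot <- 0
    for (j in 1:2)
      tot <- tot + sum(r[, j] * lucidmiss:::dmvnorm_log(Z, mu[j, ], Sigma[[j]]))
    tot
  }
  before <- qterm(matrix(0, 2, 4), rep(list(diag(4)), 2))
  for (fam in c("EII", "VII", "EEE", "VVV")) {
    gz <- m_step_gaussian_z(Z, r, fam)
    expect_gte(qterm(gz$mu, gz$Sigma), before - 1e-8)
  }
})

test_that("outcome M-step matches weighted moments", {
  Y <- withr::with_seed(14, rnorm(10))
  # hard assignment: per-cluster mean and ML variance
  lab <- rep(1:2, each = 5)
  r <- cbind(lab == 1, lab == 2) * 1
  out <- m_step_outcome(Y, r)
  expect_equal(out$gamma, c(mean(Y[1:5]), mean(Y[6:10])))
  expect_equal(out$sigma2,
               c(mean((Y[1:5] - mean(Y[1:5]))^2),
                 mean((Y[6:10] - mean(Y[6:10]))^2)))
  # uniform responsibilities: every cluster gets the overall mean
  outu <- m_step_outcome(Y, matrix(0.5, 10, 2))
  expect_equal(outu$gamma, rep(mean(Y), 2))
  # random weights against the explicit-sum oracle
  rr <- random_resp(10, 3, seed = 15)
  expect_equal(m_step_outcome(Y, rr), naive_outcome_mstep(Y, rr),
               tolerance = 1e-12)
})

test_that("outcome variance floor triggers a warning and clips", {
  Y <- rep(c(0, 1), each = 5)
  r <- cbind(Y == 0, Y == 1) * 1
  expect_warning(out <- m_step_outcome(Y, r), "clipped")
  expect_true(all(out$sigma2 >= 1e-8))
})

test_that("single-cluster imputation equals the Gaussian conditional mean", {
  params1 <- function(mu, Sigma)
    lucid_params(beta = matrix(0, 1, 2), mu = matrix(mu, 1),
                 Sigma = list(Sigma), gamma = 0, sigma2 = 1)
  for (s in 1:20) {
    m <- 2L + (s %% 3L)
    Sigma <- random_pd(m, seed = 100 + s)
    mu <- withr::with_seed(200 + s, rnorm(m))
    z <- withr::with_seed(300 + s, rnorm(m))
    miss <- rep(FALSE, m); miss[seq_len(1L + (s %% (m - 1L)))] <- TRUE
    got <- i_step_impute_row(z, miss, 1, params1(mu, Sigma))
    want <- conditional_mean(z[!miss], which(!miss), which(miss), mu, Sigma)
    expect_equal(got[miss], as.vector(want), tolerance = 1e-6)
    # density scaling is irrelevant at K = 1
    got2 <- i_step_impute_row(z, miss, 1, params1(mu, Sigma),
                              weighting = "density_scaled")
    expect_equal(got, got2, tolerance = 1e-10)
  }
})

test_that("imputation no-ops on complete rows and honours degenerate weights", {
  params <- lucid_params(beta = matrix(0, 2, 2),
                         mu = rbind(c(-1, -1), c(1, 1)),
                         Sigma = list(random_pd(2, 1), random_pd(2, 2)),
                         gamma = c(-1, 1), sigma2 = c(1, 1))
  z <- c(0.3, -0.2)
  expect_identical(i_step_impute_row(z, c(FALSE, FALSE), c(0.5, 0.5), params),
                   z)
  # all weight on cluster 1: reduces to its conditional mean regardless of
  # the density factor
  zi <- i_step_impute_row(c(0.3, 0), c(FALSE, TRUE), c(1, 0), params)
  want <- conditional_mean(0.3, 1L, 2L, params$mu[1, ], params$Sigma[[1]])
  expect_equal(zi[2], as.vector(want), tolerance = 1e-5)
  expect_error(i_step_impute_row(z, c(TRUE, TRUE), c(1, 0), params),
               "fully missing")
})

test_that("partitioned log-likelihood matches closed forms and direct sums", {
  # one standard-normal row evaluated at its mean
  p1 <- lucid_params(beta = matrix(0, 1, 2), mu = matrix(0, 1, 1),
                     Sigma = list(matrix(1)), gamma = 0, sigma2 = 1)
  part <- classify_missing_pattern(matrix(FALSE, 1, 1))
  ll <- observed_loglik(matrix(0, 1, 1), matrix(0, 1, 1), 0, part, p1)
  expect_equal(ll, 2 * (-0.5 * log(2 * pi)), tolerance = 1e-12)

  # complete data: the partitioned form equals the direct mixture sum
  fx <- make_fixture(n = 12, p = 2, m = 2, seed = 21)
  part <- classify_missing_pattern(fx$data$mask)
  ll1 <- observed_loglik(fx$data$G, fx$data$Z, fx$data$Y, part, fx$params)
  expect_equal(ll1, naive_complete_loglik(fx$data$G, fx$data$Z, fx$data$Y,
                                          fx$params), tolerance = 1e-8)

  # fully missing rows never touch the omics parameters
  Z <- fx$data$Z; Z[3, ] <- NA
  d <- lucid_data(fx$data$G, Z, fx$data$Y)
  part2 <- classify_missing_pattern(d$mask)
  pa <- fx$params
  pb <- fx$params; pb$mu <- pb$mu + 5
  la <- observed_loglik(d$G, d$Z, d$Y, part2, pa)
  lb <- observed_loglik(d$G, d$Z, d$Y, part2, pb)
  # contribution of row 3 is identical under both parameter sets
  ia <- part2$ia
  la_ic <- la - observed_loglik(d$G[ia, , drop = FALSE],
                                d$Z[ia, , drop = FALSE], d$Y[ia],
                                classify_missing_pattern(d$mask[ia, , drop = FALSE]),
                                pa)
  lb_ic <- lb - observed_loglik(d$G[ia, , drop = FALSE],
                                d$Z[ia, , drop = FALSE], d$Y[ia],
                                classify_missing_pattern(d$mask[ia, , drop = FALSE]),
                                pb)
  expect_equal(la_ic, lb_ic, tolerance = 1e-10)
})
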