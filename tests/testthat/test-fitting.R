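test_that("start-up imputation recovers exact linear structure", {
  # no partially observed rows: identity
  fx <- make_fixture(n = 20)
  part <- classify_missing_pattern(fx$data$mask)
  expect_identical(initial_impute(fx$data$Z, part), fx$data$Z)

  # two perfectly correlated columns: imputation equals the regression line
  z1 <- withr::with_seed(31, rnorm(40))
  Z <- cbind(z1, 2 * z1 + 1)
  Z[5, 2] <- NA
  part <- classify_missing_pattern(is.na(Z))
  got <- initial_impute(Z, part)
  expect_equal(unname(got[5, 2]), 2 * z1[5] + 1, tolerance = 1e-6)

  # a column uncorrelated with the others: stays near the column mean
  Z2 <- withr::with_seed(32, matrix(rnorm(300), 100, 3))
  Z2[7, 3] <- NA
  part2 <- classify_missing_pattern(is.na(Z2))
  got2 <- initial_impute(Z2, part2)
  se <- sd(Z2[-7, 3]) / sqrt(99)
  expect_lt(abs(got2[7, 3] - mean(Z2[-7, 3])), 3 * sd(Z2[-7, 3]))
  expect_false(is.na(got2[7, 3]))
})

test_that("initialisation is deterministic and sensible", {
  fx <- make_fixture(n = 80, seed = 33)
  part <- classify_missing_pattern(fx$data$mask)
  p1 <- initialize_params(fx$data, fx$data$Z, part, K = 2, seed = 5)
  p2 <- initialize_params(fx$data, fx$data$Z, part, K = 2, seed = 5)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$beta, p2$beta)

  # K = 1 closed forms
  p0 <- initialize_params(fx$data, fx$data$Z, part, K = 1, seed = 5)
  expect_equal(as.vector(p0$mu), colMeans(fx$data$Z))
  expect_equal(max(abs(p0$beta)), 0)
  expect_equal(p0$gamma, mean(fx$data$Y))
})

test_that("initial hard labels track a well-separated truth", {
  design <- sim_design(n = 300, p = 2, m = 3, K = 2)
  truth <- default_truth(design, mu_effect = 3)   # 6 SD between means
  sim <- simulate_lucid_data(design, truth, seed = 34)
  part <- classify_missing_pattern(sim$data$mask)
  init <- initialize_params(sim$data, sim$data$Z, part, K = 2, seed = 6)
  # assign each row to the nearest initial mean, compare to truth up to
  # relabelling
  d1 <- rowSums(sweep(sim$data$Z, 2, init$mu[1, ])^2)
  d2 <- rowSums(sweep(sim$data$Z, 2, init$mu[2, ])^2)
  lab <- 1L + (d2 < d1)
  acc <- max(mean(lab == sim$truth$X), mean(lab == 3L - sim$truth$X))
  expect_gte(acc, 0.95)
})

test_that("parameter counting follows the covariance family", {
  expect_identical(count_params(2, 10, 4, "VVV"), 43L)
  expect_identical(count_params(1, 7, 3, "VVV"),
                   as.integer(3 + 3 * 4 / 2 + 1 + 1))
  expect_lt(count_params(3, 2, 5, "EII"), count_params(3, 2, 5, "VVV"))
})

test_that("K = 1 fit reduces to closed-form sample moments", {
  fx <- make_fixture(n = 60, seed = 35)
  Z <- fx$data$Z; Z[1:5, ] <- NA          # a few fully missing rows
  d <- lucid_data(fx$data$G, Z, fx$data$Y)
  fit <- fit_lucid(d, fit_config(K = 1, seed = 1))
  iab <- 6:60
  expect_equal(as.vector(fit$params$mu), colMeans(Z[iab, ]), tolerance = 1e-8)
  expect_equal(fit$params$gamma, mean(fx$data$Y), tolerance = 1e-8)
  expect_equal(fit$params$sigma2, mean((fx$data$Y - mean(fx$data$Y))^2),
               tolerance = 1e-8)
  nobs <- length(iab)
  expect_equal(fit$params$Sigma[[1]], cov(Z[iab, ]) * (nobs - 1) / nobs,
               tolerance = 1e-8)
})

test_that("fits are reproducible and leave observed cells untouched", {
  design <- sim_design(n = 200, p = 3, m = 3, K = 2)
  sim <- simulate_lucid_data(design, default_truth(design), seed = 36)
  d <- inject_missing(sim$data, "sporadic_mcar", 0.15, seed = 37)
  cfg <- fit_config(K = 2, seed = 9)
  f1 <- fit_lucid(d, cfg)
  f2 <- fit_lucid(d, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  # observed cells bit-identical; imputed cells filled; fully missing rows
  # left missing
  expect_identical(f1$Z_imputed[!d$mask], d$Z[!d$mask])
  part <- f1$partition
  if (part$n_b)
    expect_false(anyNA(f1$Z_imputed[part$ib, ]))
  if (part$n_c)
    expect_true(all(is.na(f1$Z_imputed[part$ic, ])))
  # likelihood trace never decreases beyond slack
  expect_gte(min(diff(f1$loglik_trace)), -1e-6)
  # clusters come back ordered by outcome mean
  expect_true(!is.unsorted(f1$params$gamma))
})

test_that("restarts keep the best likelihood", {
  design <- sim_design(n = 150, p = 2, m = 3, K = 2)
  sim <- simulate_lucid_data(design, default_truth(design), seed = 38)
  f1 <- fit_lucid(sim$data, fit_config(K = 2, seed = 3, n_init = 1))
  f3 <- fit_lucid(sim$data, fit_config(K = 2, seed = 3, n_init = 3))
  expect_gte(f3$loglik + 1e-9, f1$loglik)
})

test_that("baselines behave per their definitions", {
  design <- sim_design(n = 200, p = 3, m = 3, K = 2)
  sim <- simulate_lucid_data(design, default_truth(design), seed = 39)
  d <- inject_missing(sim$data, "listwise_mcar", 0.5, seed = 40)
  cc <- fit_baseline(d, fit_config(K = 2, seed = 4, mode = "complete_case"))
  expect_equal(cc$n, 100)                   # exactly n/2 rows retained
  mi <- fit_baseline(d, fit_config(K = 2, seed = 4, mode = "mean_impute"))
  expect_equal(mi$n, 200)
  expect_equal(mi$partition$n_a, 200)       # all rows complete after filling
  # complete-case errors when fewer than 10*K complete rows remain
  design3 <- sim_design(n = 150, p = 3, m = 3, K = 2)
  sim3 <- simulate_lucid_data(design3, default_truth(design3), seed = 39)
  d2 <- inject_missing(sim3$data, "listwise_mcar", 0.9, seed = 41)
  expect_error(fit_baseline(d2, fit_config(K = 2, mode = "complete_case")),
               "complete rows")
})

test_that("BIC selection table is consistent", {
  design <- sim_design(n = 150, p = 2, m = 2, K = 2)
  sim <- simulate_lucid_data(design, default_truth(design, mu_effect = 1.5),
                             seed = 42)
  Z <- sim$data$Z; Z[1:15, ] <- NA
  d <- lucid_data(sim$data$G, Z, sim$data$Y)
  sel <- select_k(d, fit_config(K = c(1, 1, 2), seed = 2))
  # duplicate grid entries give identical BIC (determinism)
  expect_equal(sel$table$bic[1], sel$table$bic[2])
  # BIC recomputes from loglik with n = total rows (including fully
  # missing ones)
  expect_equal(sel$table$bic,
               -2 * sel$table$loglik + sel$table$n_params * log(150))
})
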