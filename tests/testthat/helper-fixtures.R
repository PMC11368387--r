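# Fixtures are always built in code, never stored on disk.

# small complete dataset drawn from a known two-cluster truth
make_fixture <- function(n = 20L, p = 2L, m = 2L, K = 2L, seed = 42L,
                         mu_effect = 0.5, gamma_effect = 1) {
  design <- sim_design(n = n, p = p, m = m, K = K)
  truth <- default_truth(design, mu_effect = mu_effect,
                         gamma_effect = gamma_effect)
  sim <- simulate_lucid_data(design, truth, seed = seed)
  list(data = sim$data, truth = sim$truth, params = truth, design = design)
}

# arbitrary but valid parameter values for a K=2, p=1, m=1 scalar model
scalar_params <- function() {
  lucid_params(beta = rbind(c(0, 0), c(0.4, -0.7)),
               mu = rbind(-1, 1.5),
               Sigma = list(matrix(0.8), matrix(1.3)),
               gamma = c(-0.5, 0.9), sigma2 = c(1.1, 0.6))
}

# random symmetric positive-definite matrix
random_pd <- function(m, seed = NULL) {
  gen <- function() {
    A <- matrix(stats::rnorm(m * m), m, m)
    crossprod(A) + diag(0.5, m)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# random valid responsibility matrix
random_resp <- function(n, K, seed = NULL) {
  gen <- function() {
    r <- matrix(stats::runif(n * K), n, K)
    r / rowSums(r)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
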