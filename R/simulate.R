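# Synthetic-data generator following the model's generative process:
# exposures G drawn iid standard normal, latent labels X from the softmax
# of G, omics Z multivariate Gaussian given X, outcome Y Gaussian given X;
# plus missingness injectors for the list-wise and sporadic patterns.

#' Simulation design
#'
#' @param n number of observations (default 10000, split downstream into
#'   8000 training and 2000 validation rows).
#' @param p number of exposures.
#' @param m number of omics features.
#' @param K number of latent clusters.
#' @return a `sim_design` list.
#' @export
sim_design <- function(n = 10000L, p = 10L, m = 4L, K = 2L) {
  stopifnot(n >= 2L, p >= 1L, m >= 1L, K >= 1L)
  structure(list(n = as.integer(n), p = as.integer(p), m = as.integer(m),
                 K = as.integer(K)), class = "sim_design")
}

#' Default ground-truth parameters for the simulation design
#'
#' A fixed, documented truth with detectable effects for the two-cluster
#' design: cluster 2's exposure log-odds are `beta_effect` on the first
#' five exposures (zero elsewhere, zero intercept), omics means sit at
#' -`mu_effect` and +`mu_effect` on every feature with identity
#' covariances, and the outcome means are -1 and +1 with unit variances.
#' For `K > 2` the clusters are spread evenly on the same scales.
#'
#' @param design a [sim_design].
#' @param beta_effect log-odds-ratio per active exposure.
#' @param mu_effect half-distance between cluster omics means per feature.
#' @param gamma_effect half-distance between cluster outcome means.
#' @return A [lucid_params] object.
#' @export
default_truth <- function(design = sim_design(), beta_effect = 0.3,
                          mu_effect = 0.5, gamma_effect = 1) {
  K <- design$K; p <- design$p; m <- design$m
  beta <- matrix(0, K, p + 1L)
  n_active <- min(5L, p)
  if (K > 1L)
    for (j in 2:K)
      beta[j, 1L + seq_len(n_active)] <- beta_effect * (j - 1)
  levels <- if (K == 1L) 0 else seq(-1, 1, length.out = K)
  mu <- matrix(rep(levels * mu_effect, m), K, m)
  Sigma <- rep(list(diag(1, m)), K)
  gamma <- levels * gamma_effect
  sigma2 <- rep(1, K)
  lucid_params(beta = beta, mu = mu, Sigma = Sigma, gamma = gamma,
               sigma2 = sigma2, cov_model = "VVV")
}

#' Simulate a complete dataset from the model
#'
#' @param design a [sim_design].
#' @param params true parameters, defaulting to [default_truth].
#' @param seed integer seed.
#' @return list with `data` (a [lucid_data], no missing cells) and `truth`
#'   (a `sim_truth`: the parameters, labels `X`, design, seed).
#' @export
simulate_lucid_data <- function(design = sim_design(),
                                params = default_truth(design),
                                seed = 1L) {
  stopifnot(inherits(design, "sim_design"), inherits(params, "lucid_params"))
  if (params$K != design$K || params$p != design$p || params$m != design$m)
    stop("params dimensions do not match the design")
  n <- design$n; p <- design$p; m <- design$m; K <- design$K
  sim <- withr::with_seed(seed, {
    G <- matrix(stats::rnorm(n * p), n, p)
    S <- softmax_probs(G, params$beta)
    u <- stats::runif(n)
    if (K == 1L) {
      X <- rep(1L, n)
    } else {
      cum <- t(apply(S, 1, cumsum))   # n x K row-wise cumulative sums
      X <- 1L + rowSums(u > cum)
    }
    Z <- matrix(0, n, m)
    for (j in seq_len(K)) {
      idx <- which(X == j)
      if (!length(idx)) next
      ch <- chol(params$Sigma[[j]])
      E <- matrix(stats::rnorm(length(idx) * m), length(idx), m)
      Z[idx, ] <- sweep(E %*% ch, 2, params$mu[j, ], `+`)
    }
    Y <- stats::rnorm(n, params$gamma[X], sqrt(params$sigma2[X]))
    list(G = G, Z = Z, Y = Y, X = X)
  })
  data <- lucid_data(sim$G, sim$Z, sim$Y)
  truth <- structure(list(params = params, X = sim$X, design = design,
                          seed = seed, mechanism = "none", missing_ratio = 0),
                     class = "sim_truth")
  list(data = data, truth = truth)
}

#' Split a simulated dataset into training and validation parts
#'
#' @param data a [lucid_data].
#' @param truth the matching `sim_truth` (labels are carried along).
#' @param n_train,n_valid sizes of the disjoint split (defaults 8000/2000).
#' @param seed integer seed.
#' @return list with `train` and `valid`, each a list of `data`, `labels`
#'   and the row `indices` into the original dataset.
#' @export
train_validation_split <- function(data, truth, n_train = 8000L,
                                   n_valid = 2000L, seed = 1L) {
  n <- data$n
  if (n_train + n_valid > n) stop("split larger than the dataset")
  idx <- withr::with_seed(seed, sample.int(n, n_train + n_valid))
  tr <- sort(idx[seq_len(n_train)])
  va <- sort(idx[n_train + seq_len(n_valid)])
  subset_rows <- function(rows) list(
    data = lucid_data(data$G[rows, , drop = FALSE],
                      data$Z[rows, , drop = FALSE],
                      data$Y[rows], data$row_ids[rows]),
    labels = truth$X[rows], indices = rows)
  list(train = subset_rows(tr), valid = subset_rows(va))
}

#' Draw a per-replicate subsample of training rows
#'
#' @param train the `train` element of [train_validation_split].
#' @param n_sub subsample size (default 2000).
#' @param seed integer seed.
#' @return a list like `train` restricted to the subsample.
#' @export
subsample_training <- function(train, n_sub = 2000L, seed = 1L) {
  n <- train$data$n
  if (n_sub > n) stop("subsample larger than the training set")
  rows <- withr::with_seed(seed, sort(sample.int(n, n_sub)))
  list(data = lucid_data(train$data$G[rows, , drop = FALSE],
                         train$data$Z[rows, , drop = FALSE],
                         train$data$Y[rows], train$data$row_ids[rows]),
       labels = train$labels[rows], indices = train$indices[rows])
}

#' Inject missingness into the omics matrix
#'
#' Three mechanisms. `listwise_mcar`: exactly `round(ratio * n)` rows,
#' chosen uniformly, get their whole omics row removed. `listwise_mar_y`:
#' the same exact count, but rows are drawn without replacement with
#' probability proportional to a logistic function of the outcome,
#' calibrated so the top outcome quartile's missingness odds are three
#' times the bottom quartile's -- higher-outcome rows go missing more
#' often (missing at random given Y). `sporadic_mcar`: each cell is
#' removed independently with probability `ratio`; rows that happen to
#' lose every cell simply become list-wise missing.
#'
#' @param data a [lucid_data] with complete Z.
#' @param mechanism one of `"listwise_mcar"`, `"listwise_mar_y"`,
#'   `"sporadic_mcar"`.
#' @param ratio missing ratio in `[0, 0.9]`.
#' @param seed integer seed.
#' @return a new [lucid_data] with the mask applied.
#' @export
inject_missing <- function(data, mechanism = c("listwise_mcar",
                                               "listwise_mar_y",
                                               "sporadic_mcar"),
                           ratio, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(ratio >= 0, ratio <= 0.9)
  n <- data$n; m <- data$m
  Z <- data$Z
  if (ratio == 0) return(data)
  if (mechanism == "sporadic_mcar") {
    mask <- withr::with_seed(seed,
      matrix(stats::runif(n * m) < ratio, n, m))
  } else {
    n_miss <- round(ratio * n)
    rows <- withr::with_seed(seed, {
      if (mechanism == "listwise_mcar") {
        sample.int(n, n_miss)
      } else {
        Y <- data$Y
        q <- stats::quantile(Y, c(0.25, 0.75))
        lo <- mean(Y[Y <= q[1]]); hi <- mean(Y[Y >= q[2]])
        b <- log(3) / (hi - lo)   # top-quartile odds 3x bottom-quartile
        # centre so the average missingness probability matches the ratio
        a <- tryCatch(stats::uniroot(function(a)
          mean(stats::plogis(a + b * Y)) - ratio,
          lower = -50, upper = 50)$root, error = function(e) 0)
        sample.int(n, n_miss, prob = stats::plogis(a + b * Y))
      }
    })
    mask <- matrix(FALSE, n, m)
    mask[rows, ] <- TRUE
  }
  if (sum(rowSums(mask) == 0L) < 2L)
    stop("missing ratio leaves fewer than 2 complete rows")
  Z[mask] <- NA_real_
  lucid_data(data$G, Z, data$Y, data$row_ids)
}
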