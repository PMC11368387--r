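# Out-of-sample prediction, AUC-based clustering accuracy, estimate
# alignment against a known truth, and the replication-study driver that
# benchmarks the integrated fit against the baselines across missing
# ratios.

#' Posterior cluster probabilities for new observations
#'
#' Computes responsibilities for new data from fitted parameters. By
#' default the outcome is not used (out-of-sample cluster prediction), so
#' r is proportional to S(X=j | G) * phi(Z | mu_j, Sigma_j). Rows of
#' `Z_new` with missing cells use the marginal Gaussian density of their
#' observed coordinates; fully missing rows fall back to the exposure
#' model alone (plus the outcome term when `use_outcome = TRUE`).
#'
#' @param params a [lucid_params] or `lucid_fit` object.
#' @param G_new n_new x p exposure matrix.
#' @param Z_new n_new x m omics matrix, possibly with `NA` cells; may be
#'   `NULL` to predict from exposures alone.
#' @param Y_new outcome vector, required when `use_outcome = TRUE`.
#' @param use_outcome include the outcome density term.
#' @return list with `r` (n_new x K posterior matrix) and `labels`
#'   (argmax cluster per row, ties to the lower index).
#' @export
predict_posterior <- function(params, G_new, Z_new = NULL, Y_new = NULL,
                              use_outcome = FALSE) {
  if (inherits(params, "lucid_fit")) params <- params$params
  stopifnot(inherits(params, "lucid_params"))
  G_new <- as.matrix(G_new)
  if (ncol(G_new) != params$p) stop("G_new has wrong number of columns")
  K <- params$K
  lp <- softmax_probs(G_new, params$beta, log = TRUE)
  if (use_outcome) {
    if (is.null(Y_new)) stop("Y_new required when use_outcome = TRUE")
    for (j in seq_len(K))
      lp[, j] <- lp[, j] + stats::dnorm(Y_new, params$gamma[j],
                                        sqrt(params$sigma2[j]), log = TRUE)
  }
  if (!is.null(Z_new)) {
    Z_new <- as.matrix(Z_new)
    if (ncol(Z_new) != params$m) stop("Z_new has wrong number of columns")
    if (nrow(Z_new) != nrow(G_new)) stop("Z_new and G_new row mismatch")
    obs_pattern <- !is.na(Z_new)
    patterns <- unique(obs_pattern)
    for (k in seq_len(nrow(patterns))) {
      pat <- patterns[k, ]
      rows <- which(apply(obs_pattern, 1, function(x) all(x == pat)))
      if (!any(pat)) next                      # fully missing: S (and Y) only
      for (j in seq_len(K))
        lp[rows, j] <- lp[rows, j] +
          dmvnorm_log(Z_new[rows, pat, drop = FALSE],
                      params$mu[j, pat],
                      params$Sigma[[j]][pat, pat, drop = FALSE])
    }
  }
  r <- exp(lp - row_logsumexp(lp))
  r <- r / rowSums(r)
  list(r = r, labels = max.col(r, ties.method = "first"))
}

#' Predict the outcome for new observations
#'
#' The posterior-mixture mean: Y_hat_i = sum_j r_ij gamma_j.
#'
#' @param r n x K posterior matrix (e.g. from [predict_posterior]).
#' @param params a [lucid_params] or `lucid_fit`.
#' @return numeric vector of predicted outcomes.
#' @export
predict_outcome <- function(r, params) {
  if (inherits(params, "lucid_fit")) params <- params$params
  as.vector(as.matrix(r) %*% params$gamma)
}

#' Clustering accuracy as rank (Mann-Whitney) AUC
#'
#' Compares posterior inclusion probabilities to known binary labels: the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, with the usual half-credit for ties (computed from mean
#' ranks). Invariant to any strictly monotone transform of the scores.
#'
#' @param pip numeric score vector (posterior probability of the positive
#'   cluster).
#' @param labels binary vector (two distinct values; the larger one is the
#'   positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_pip <- function(pip, labels) {
  labels <- as.numeric(as.factor(labels))
  if (length(unique(labels)) != 2L)
    stop("labels must contain exactly two classes")
  pos <- labels == max(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  rk <- rank(pip)                 # mean ranks handle ties
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Align estimated parameters with a known truth and report deltas
#'
#' Mixture parameters are only identified up to cluster relabelling, so
#' before comparing an estimate to the generating truth the cluster labels
#' are permuted to match: both parameter sets are ordered by increasing
#' outcome mean gamma; if the estimated gammas tie, the permutation
#' minimising the total distance between omics means is used instead.
#'
#' @param estimate,truth [lucid_params] objects with equal K.
#' @return list with `estimate` (relabelled), `delta` (per-parameter
#'   estimate minus truth: `beta`, `mu`, `gamma`, `sigma2`) and the
#'   permutation applied.
#' @export
align_and_bias <- function(estimate, truth) {
  if (inherits(estimate, "lucid_fit")) estimate <- estimate$params
  stopifnot(inherits(estimate, "lucid_params"), inherits(truth, "lucid_params"))
  if (estimate$K != truth$K) stop("cluster counts differ")
  K <- estimate$K
  truth_ord <- order(truth$gamma)
  ties <- any(duplicated(truth$gamma)) || any(duplicated(estimate$gamma))
  if (!ties) {
    perm <- order(estimate$gamma)[order(truth_ord)]
  } else {
    perms <- all_permutations(K)
    cost <- vapply(seq_len(nrow(perms)), function(i)
      sum((estimate$mu[perms[i, ], , drop = FALSE] - truth$mu)^2), 0)
    perm <- perms[which.min(cost), ]
  }
  est <- permute_params(estimate, perm)
  list(estimate = est,
       delta = list(beta = est$beta - truth$beta,
                    mu = est$mu - truth$mu,
                    gamma = est$gamma - truth$gamma,
                    sigma2 = est$sigma2 - truth$sigma2),
       perm = perm)
}

all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(K - 1L)
  out <- NULL
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                   sub[, seq(pos, K - 1L)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

#' Replication study comparing methods across missing ratios
#'
#' Reproduces the simulation benchmark: one large dataset is generated
#' from the truth and split into training and validation parts; each
#' replicate subsamples the training rows, injects missingness at each
#' ratio, fits each method, and evaluates the posterior of cluster
#' membership (without the outcome) on the fixed validation set against
#' the known labels via AUC. Parameter estimates are aligned to the truth
#' before aggregation.
#'
#' @param design a [sim_design] for the source dataset.
#' @param truth generating parameters (default [default_truth]).
#' @param mechanism missingness mechanism for [inject_missing].
#' @param ratio_grid vector of missing ratios.
#' @param methods subset of `c("lucid", "complete_case", "mean_impute")`.
#' @param n_reps number of replicates.
#' @param n_sub training subsample size per replicate.
#' @param n_train,n_valid split sizes.
#' @param seed master seed; every replicate/ratio cell derives its own.
#' @param cov_model covariance family for all fits.
#' @param verbose print progress.
#' @return list with `results` (long data.frame: method, ratio, replicate,
#'   auc, one column per scalar parameter estimate, converged, error),
#'   `aggregate` (mean/SD of each estimate and median/SD of AUC per
#'   method x ratio), `truth`, `n_failed`.
#' @export
run_replication_study <- function(design = sim_design(),
                                  truth = default_truth(design),
                                  mechanism = "listwise_mcar",
                                  ratio_grid = c(0.1, 0.3, 0.5),
                                  methods = c("lucid", "complete_case",
                                              "mean_impute"),
                                  n_reps = 50L, n_sub = 2000L,
                                  n_train = 8000L, n_valid = 2000L,
                                  seed = 1L, cov_model = "VVV",
                                  verbose = FALSE) {
  stopifnot(n_reps >= 2L)
  methods <- match.arg(methods, c("lucid", "complete_case", "mean_impute"),
                       several.ok = TRUE)
  sim <- simulate_lucid_data(design, truth, seed = seed)
  split <- train_validation_split(sim$data, sim$truth, n_train, n_valid,
                                  seed = seed + 1L)
  valid <- split$valid
  valid_pos <- valid$labels == design$K   # highest-gamma cluster as positive
  param_names <- scalar_param_names(truth)
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    sub <- subsample_training(split$train, n_sub, seed = seed + 100L + rep_i)
    for (ratio in ratio_grid) {
      cell_seed <- seed + 10000L + rep_i * 37L + round(ratio * 1000L)
      dat <- if (ratio > 0)
        inject_missing(sub$data, mechanism, ratio, seed = cell_seed) else
        sub$data
      for (method in methods) {
        cfg <- fit_config(K = design$K, cov_model = cov_model,
                          seed = cell_seed,
                          mode = if (method == "lucid") "lucid" else method)
        fit <- tryCatch(
          if (method == "lucid") fit_lucid(dat, cfg) else
            fit_baseline(dat, cfg),
          error = function(e) e)
        if (inherits(fit, "error")) {
          row <- data.frame(method = method, ratio = ratio,
                            replicate = rep_i, auc = NA_real_,
                            converged = FALSE,
                            error = conditionMessage(fit))
          row[param_names] <- NA_real_
        } else {
          aligned <- align_and_bias(fit$params, truth)
          pred <- predict_posterior(aligned$estimate, valid$data$G,
                                    valid$data$Z)
          auc <- auc_pip(pred$r[, design$K], valid_pos)
          row <- data.frame(method = method, ratio = ratio,
                            replicate = rep_i, auc = auc,
                            converged = fit$converged, error = NA_character_)
          row[param_names] <- scalar_param_values(aligned$estimate)
        }
        rows[[length(rows) + 1L]] <- row
      }
      if (verbose)
        message(sprintf("replicate %d ratio %.2f done", rep_i, ratio))
    }
  }
  results <- do.call(rbind, rows)
  ok <- !is.na(results$auc)
  agg <- do.call(rbind, lapply(split(results[ok, ], list(results$method[ok],
                                                         results$ratio[ok]),
                                     drop = TRUE), function(d) {
    est <- d[param_names]
    data.frame(method = d$method[1L], ratio = d$ratio[1L], n_ok = nrow(d),
               auc_median = stats::median(d$auc), auc_sd = stats::sd(d$auc),
               t(colMeans(est)),
               stats::setNames(as.data.frame(t(apply(est, 2, stats::sd))),
                               paste0(param_names, "_sd")))
  }))
  rownames(agg) <- NULL
  list(results = results, aggregate = agg, truth = truth,
       n_failed = sum(!ok))
}

# flatten the identifiable scalar parameters of a parameter set: non-
# reference beta rows, all omics means, outcome means and variances
scalar_param_names <- function(params) {
  K <- params$K; p <- params$p; m <- params$m
  nm <- c()
  if (K > 1L)
    for (j in 2:K) nm <- c(nm, paste0("beta", j, "_", 0:p))
  for (j in seq_len(K)) nm <- c(nm, paste0("mu", j, "_", seq_len(m)))
  c(nm, paste0("gamma", seq_len(K)), paste0("sigma2_", seq_len(K)))
}

scalar_param_values <- function(params) {
  K <- params$K
  v <- c()
  if (K > 1L) v <- as.vector(t(params$beta[-1L, , drop = FALSE]))
  c(v, as.vector(t(params$mu)), params$gamma, params$sigma2)
}

# matching truth vector, used when comparing aggregates to the truth
scalar_param_truth <- function(truth) scalar_param_values(truth)
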