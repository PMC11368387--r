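# Drives the full fitting loop: start-up imputation, parameter
# initialisation, E/M/I iteration with the partitioned likelihood as
# convergence monitor, BIC model selection over K, and the complete-case
# and mean-imputation baseline fitters.

#' Fit configuration
#'
#' @param K number of latent clusters (integer >= 1), or a grid for
#'   [select_k].
#' @param cov_model covariance family, one of `"EII"`, `"VII"`, `"EEE"`,
#'   `"VVV"`.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the change in the partitioned
#'   log-likelihood between iterations.
#' @param tol_type `"absolute"` (default) or `"relative"` change.
#' @param seed integer seed controlling initialisation.
#' @param n_init number of random restarts; best final log-likelihood wins.
#' @param mode `"lucid"` for the integrated fit, or a baseline:
#'   `"complete_case"`, `"mean_impute"`.
#' @param i_weights weighting of the I-step imputation solve:
#'   `"responsibility"` (default; the exact Q-function maximiser, keeps
#'   the likelihood ascent property) or `"density_scaled"` (responsibility
#'   times the omics density at the previous imputed row).
#' @return A `fit_config` list.
#' @export
fit_config <- function(K = 2L, cov_model = "VVV", max_iter = 1000L,
                       tol = 1e-6, tol_type = c("absolute", "relative"),
                       seed = 1L, n_init = 1L,
                       mode = c("lucid", "complete_case", "mean_impute"),
                       i_weights = c("responsibility", "density_scaled")) {
  stopifnot(all(K >= 1L), tol > 0, max_iter >= 1L, n_init >= 1L)
  structure(list(K = as.integer(K),
                 cov_model = match.arg(cov_model, c("EII", "VII", "EEE", "VVV")),
                 max_iter = as.integer(max_iter), tol = tol,
                 tol_type = match.arg(tol_type),
                 seed = as.integer(seed), n_init = as.integer(n_init),
                 mode = match.arg(mode),
                 i_weights = match.arg(i_weights)),
            class = "fit_config")
}

#' Start-up imputation of sporadically missing omics cells
#'
#' Fills the missing cells of partially observed rows by iterative
#' column-wise regression: starting from column means, each incomplete
#' column is repeatedly regressed on all other columns using the rows
#' where it is observed, and its missing cells are replaced by the fitted
#' values (5 sweeps). Fully missing rows are left untouched -- they enter
#' the likelihood through the partition, not through imputation.
#'
#' @param Z n x m omics matrix with `NA` cells.
#' @param partition the row partition from [classify_missing_pattern].
#' @param n_sweeps number of passes over the incomplete columns.
#' @return `Z` with the cells of partially observed rows filled.
#' @export
initial_impute <- function(Z, partition, n_sweeps = 5L) {
  if (!partition$n_b) return(Z)
  iab <- c(partition$ia, partition$ib)
  Zs <- Z[iab, , drop = FALSE]
  mask <- is.na(Zs)
  mu_col <- colMeans(Zs, na.rm = TRUE)
  for (j in which(colSums(mask) > 0L)) Zs[mask[, j], j] <- mu_col[j]
  if (partition$n_a >= 2L && ncol(Zs) > 1L) {
    for (s in seq_len(n_sweeps)) {
      for (j in which(colSums(mask) > 0L)) {
        obs <- !mask[, j]
        X <- cbind(1, Zs[, -j, drop = FALSE])
        fit <- stats::lm.fit(X[obs, , drop = FALSE], Zs[obs, j])
        coef <- fit$coefficients
        coef[is.na(coef)] <- 0
        Zs[mask[, j], j] <- as.vector(X[mask[, j], , drop = FALSE] %*% coef)
      }
    }
  }
  Z[iab, ] <- Zs
  Z
}

#' Initial parameter values
#'
#' Seeded k-means on the (imputed) omics rows of the observed subset gives
#' hard cluster labels; cluster moments of Z and Y give the Gaussian
#' starts, and a multinomial-logit fit of the labels on G gives the
#' exposure coefficients. Fully missing rows are excluded from the label
#' fit; for the outcome moments they are assigned to the cluster with the
#' highest softmax probability under the initial coefficients.
#'
#' @param data a [lucid_data] object.
#' @param Z_filled omics matrix after [initial_impute].
#' @param partition row partition.
#' @param K number of clusters.
#' @param seed integer seed for k-means.
#' @param cov_model covariance family.
#' @param max_reseed re-draws allowed when k-means returns an empty or
#'   near-empty cluster.
#' @return A [lucid_params] object.
#' @export
initialize_params <- function(data, Z_filled, partition, K, seed,
                              cov_model = "VVV", max_reseed = 10L) {
  iab <- c(partition$ia, partition$ib)
  if (length(iab) < K) stop("fewer observed omics rows than clusters")
  Zs <- Z_filled[iab, , drop = FALSE]
  m <- ncol(Zs)
  if (K == 1L) {
    labels <- rep(1L, length(iab))
  } else {
    labels <- NULL
    for (try in seq_len(max_reseed)) {
      km <- withr::with_seed(seed + (try - 1L) * 1000L,
        stats::kmeans(Zs, centers = K, nstart = 1L, iter.max = 50L))
      if (min(table(factor(km$cluster, levels = seq_len(K)))) >= 2L) {
        labels <- km$cluster
        break
      }
    }
    if (is.null(labels)) stop("k-means initialisation produced an empty cluster ",
                              max_reseed, " times")
  }
  mu <- matrix(0, K, m)
  r_hard <- matrix(0, length(iab), K)
  r_hard[cbind(seq_along(labels), labels)] <- 1
  gz <- m_step_gaussian_z(Zs, r_hard, cov_model)
  beta <- m_step_beta(data$G[iab, , drop = FALSE], r_hard)
  # outcome moments over all rows: ic rows take their most probable
  # cluster under the exposure model (initialisation only)
  lab_all <- integer(data$n)
  lab_all[iab] <- labels
  if (partition$n_c) {
    S <- softmax_probs(data$G[partition$ic, , drop = FALSE], beta)
    lab_all[partition$ic] <- max.col(S, ties.method = "first")
  }
  r_all <- matrix(0, data$n, K)
  r_all[cbind(seq_len(data$n), lab_all)] <- 1
  out <- m_step_outcome(data$Y, r_all)
  lucid_params(beta = beta, mu = gz$mu, Sigma = gz$Sigma,
               gamma = out$gamma, sigma2 = out$sigma2, cov_model = cov_model)
}

#' Number of free parameters of a fitted model
#'
#' Counts (K-1)(p+1) exposure coefficients, K*m omics means, the
#' covariance-family-specific count (VVV: K m(m+1)/2; EEE: m(m+1)/2;
#' VII: K; EII: 1), K outcome means and K outcome variances.
#'
#' @param K,p,m model dimensions.
#' @param cov_model covariance family tag.
#' @return integer parameter count.
#' @export
count_params <- function(K, p, m, cov_model = "VVV") {
  cov_model <- match.arg(cov_model, c("EII", "VII", "EEE", "VVV"))
  n_sigma <- switch(cov_model,
                    VVV = K * m * (m + 1) / 2,
                    EEE = m * (m + 1) / 2,
                    VII = K,
                    EII = 1)
  as.integer((K - 1) * (p + 1) + K * m + n_sigma + 2 * K)
}

# one full fit from a single initialisation seed
fit_lucid_single <- function(data, partition, config, seed) {
  K <- config$K[1L]
  Zfill <- initial_impute(data$Z, partition)
  params <- initialize_params(data, Zfill, partition, K, seed,
                              config$cov_model)
  iab <- c(partition$ia, partition$ib)
  G <- data$G; Y <- data$Y
  l1 <- observed_loglik(G, Zfill, Y, partition, params)
  trace <- l1
  converged <- FALSE
  monotone <- TRUE
  r <- NULL
  for (t in seq_len(config$max_iter)) {
    # E-step: full responsibilities on observed rows, partitioned ones on
    # list-wise missing rows
    r <- matrix(0, data$n, K)
    r[iab, ] <- responsibilities_complete(G[iab, , drop = FALSE],
                                          Zfill[iab, , drop = FALSE],
                                          Y[iab], params)
    if (partition$n_c)
      r[partition$ic, ] <- responsibilities_listwise(
        G[partition$ic, , drop = FALSE], Y[partition$ic], params)
    # M-step
    beta <- m_step_beta(G, r, beta_init = params$beta)
    gz <- m_step_gaussian_z(Zfill[iab, , drop = FALSE],
                            r[iab, , drop = FALSE], config$cov_model)
    out <- m_step_outcome(Y, r)
    params <- lucid_params(beta = beta, mu = gz$mu, Sigma = gz$Sigma,
                           gamma = out$gamma, sigma2 = out$sigma2,
                           cov_model = config$cov_model)
    # I-step on sporadically missing rows
    if (partition$n_b)
      Zfill <- i_step(Zfill, data$mask, partition$ib, r, params,
                      weighting = config$i_weights)
    l2 <- observed_loglik(G, Zfill, Y, partition, params)
    trace <- c(trace, l2)
    if (l2 < l1 - 1e-6) monotone <- FALSE
    eps <- if (config$tol_type == "relative") abs(l2 - l1) / abs(l1) else
      abs(l2 - l1)
    l1 <- l2
    if (eps < config$tol) { converged <- TRUE; break }
  }
  # final responsibilities under the converged parameters
  r <- matrix(0, data$n, K)
  r[iab, ] <- responsibilities_complete(G[iab, , drop = FALSE],
                                        Zfill[iab, , drop = FALSE],
                                        Y[iab], params)
  if (partition$n_c)
    r[partition$ic, ] <- responsibilities_listwise(
      G[partition$ic, , drop = FALSE], Y[partition$ic], params)
  list(params = params, r = r, Zfill = Zfill, trace = trace,
       converged = converged && monotone, monotone = monotone)
}

#' Fit the LUCID model with incomplete omics data
#'
#' Runs the modified EM algorithm: an E-step computing responsibilities
#' (full ones for observed rows, partitioned ones for list-wise missing
#' rows), an M-step updating the exposure coefficients and outcome moments
#' on all rows and the omics Gaussians on observed rows only, and an
#' I-step re-imputing sporadically missing cells from the current mixture
#' parameters. Iterates until the partitioned log-likelihood changes by
#' less than `tol` or `max_iter` is reached. With `n_init > 1`, the
#' restarts differ in their k-means seed and the best final log-likelihood
#' is kept. Clusters are relabelled in increasing order of the outcome
#' mean `gamma` so output order is deterministic.
#'
#' @param data a [lucid_data] object.
#' @param config a [fit_config]; its `mode` must be `"lucid"` (see
#'   [fit_baseline] for the baselines).
#' @param ... convenience overrides passed to [fit_config] when `config`
#'   is missing (e.g. `fit_lucid(data, K = 3)`).
#' @return A `lucid_fit` object: `params`, responsibilities `r`,
#'   `Z_imputed` (observed cells untouched; fully missing rows left `NA`),
#'   `loglik_trace`, `loglik`, `bic`, `n_params`, `converged`, `partition`,
#'   `config`, `seed`.
#' @export
fit_lucid <- function(data, config = fit_config(...), ...) {
  stopifnot(inherits(data, "lucid_data"), inherits(config, "fit_config"))
  if (config$mode != "lucid")
    return(fit_baseline(data, config))
  validate_lucid_data(data)
  partition <- classify_missing_pattern(data$mask)
  best <- NULL
  errors <- character(0)
  for (s in seq_len(config$n_init)) {
    seed_s <- config$seed + (s - 1L) * 101L
    res <- tryCatch(fit_lucid_single(data, partition, config, seed_s),
                    error = function(e) e)
    if (inherits(res, "error")) { errors <- c(errors, conditionMessage(res)); next }
    if (is.null(best) || max(res$trace) > max(best$trace)) {
      res$seed <- seed_s
      best <- res
    }
  }
  if (is.null(best))
    stop("all restarts failed: ", paste(unique(errors), collapse = "; "))
  finish_fit(data, partition, best, config)
}

# relabel by increasing gamma, assemble the public fit object
finish_fit <- function(data, partition, res, config) {
  K <- config$K[1L]
  perm <- order(res$params$gamma)
  params <- permute_params(res$params, perm)
  r <- res$r[, perm, drop = FALSE]
  # expose imputations only where cells were actually missing; list-wise
  # missing rows stay NA
  Z_imputed <- data$Z
  if (partition$n_b) {
    ib <- partition$ib
    Z_imputed[ib, ][data$mask[ib, , drop = FALSE]] <-
      res$Zfill[ib, ][data$mask[ib, , drop = FALSE]]
  }
  ll <- res$trace[length(res$trace)]
  npar <- count_params(K, data$p, data$m, config$cov_model)
  structure(
    list(params = params, r = r, Z_imputed = Z_imputed,
         loglik_trace = res$trace, loglik = ll,
         bic = -2 * ll + npar * log(data$n), n_params = npar,
         converged = res$converged, partition = partition,
         config = config, seed = res$seed, n = data$n),
    class = "lucid_fit")
}

#' @export
print.lucid_fit <- function(x, ...) {
  cat(sprintf("lucid_fit: K = %d (%s), n = %d, log-lik = %.3f, BIC = %.2f\n",
              x$params$K, x$params$cov_model, x$n, x$loglik, x$bic))
  cat(sprintf("  rows: %d complete / %d sporadic / %d list-wise missing; %sconverged in %d iterations\n",
              x$partition$n_a, x$partition$n_b, x$partition$n_c,
              if (x$converged) "" else "NOT ", length(x$loglik_trace) - 1L))
  cat("  cluster outcome means gamma:", format(x$params$gamma, digits = 4), "\n")
  invisible(x)
}

#' Baseline fitters: complete-case and mean imputation
#'
#' `complete_case` drops every row with any missing omics cell and fits
#' the complete-data model on the remainder. `mean_impute` replaces every
#' missing cell (including fully missing rows) by its column mean over
#' observed cells and fits the complete-data model on all rows.
#'
#' @param data a [lucid_data] object.
#' @param config a [fit_config] with `mode` set to one of the baselines.
#' @param ... overrides passed to [fit_config] when `config` is missing.
#' @return A `lucid_fit` object (for `complete_case` its `n` and partition
#'   refer to the retained subset).
#' @export
fit_baseline <- function(data, config = fit_config(...), ...) {
  stopifnot(inherits(data, "lucid_data"))
  mode <- config$mode
  if (mode == "lucid") stop("config mode must be a baseline")
  sub_config <- config
  sub_config$mode <- "lucid"
  if (mode == "complete_case") {
    part <- classify_missing_pattern(data$mask)
    if (part$n_a < 10L * config$K[1L])
      stop("complete-case analysis needs at least 10*K complete rows (has ",
           part$n_a, ")")
    keep <- part$ia
    sub <- lucid_data(data$G[keep, , drop = FALSE],
                      data$Z[keep, , drop = FALSE],
                      data$Y[keep], data$row_ids[keep])
    return(fit_lucid(sub, sub_config))
  }
  # mean imputation: column means over observed cells
  Z <- data$Z
  mu_col <- colMeans(Z, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) Z[is.na(Z[, j]), j] <- mu_col[j]
  filled <- lucid_data(data$G, Z, data$Y, data$row_ids)
  fit_lucid(filled, sub_config)
}

#' Select the number of clusters by BIC
#'
#' Fits the model for each K in a grid under the same seed policy and
#' picks the K minimising BIC = -2 log-lik + n_params log(n), with n the
#' total number of rows (list-wise missing rows contribute likelihood
#' terms, so they count).
#'
#' @param data a [lucid_data] object.
#' @param config a [fit_config] whose `K` holds the grid.
#' @param ... overrides passed to [fit_config] when `config` is missing.
#' @return list with `table` (data.frame of K, loglik, bic, n_params,
#'   converged), `best_K`, `fits` (per-K `lucid_fit` or `NULL` on
#'   failure), `best` (the winning fit).
#' @export
select_k <- function(data, config = fit_config(...), ...) {
  grid <- config$K
  fits <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$K <- grid[i]
    f <- tryCatch(fit_lucid(data, cfg), error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(K = grid[i], loglik = NA_real_, bic = NA_real_,
                              n_params = NA_integer_, converged = FALSE,
                              error = conditionMessage(f))
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(K = grid[i], loglik = f$loglik, bic = f$bic,
                              n_params = f$n_params, converged = f$converged,
                              error = NA_character_)
    }
  }
  table <- do.call(rbind, rows)
  if (all(is.na(table$bic))) stop("no K in the grid could be fitted")
  best_i <- which.min(table$bic)
  list(table = table, best_K = grid[best_i], fits = fits,
       best = fits[[best_i]])
}
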