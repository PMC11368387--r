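# Delimited-text readers and writers. Missing omics cells are empty
# strings or the literal "NA" on disk and become mask entries in memory;
# categorical exposure columns are dummy-coded with the first level as
# reference.

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      na.strings = c("NA", ""), check.names = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) stop("failed to read ", path, ": ",
                             conditionMessage(e)))
  df
}

# dummy-code any non-numeric columns, first level as reference
encode_exposures <- function(df) {
  is_num <- vapply(df, is.numeric, TRUE)
  if (all(is_num)) return(as.matrix(df))
  out <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- v
    } else {
      f <- factor(v)
      for (lev in levels(f)[-1L])
        out[[paste0(nm, "_", lev)]] <- as.numeric(f == lev)
    }
  }
  as.matrix(as.data.frame(out, check.names = FALSE))
}

#' Read a LUCID dataset from delimited text files
#'
#' Either three files (exposures, omics, outcome; row alignment is
#' positional) or one wide file whose column names carry group prefixes
#' (`G_`, `Z_`, `Y` / `Y_...`). Files may be CSV or TSV (by extension);
#' missing omics cells are empty or `"NA"`. Non-numeric exposure columns
#' are dummy-coded with the first level as reference.
#'
#' @param g_file,z_file,y_file paths for the three-file layout.
#' @param wide_file path for the one-file layout (overrides the others).
#' @param id_col optional name of an identifier column in the wide file.
#' @return a [lucid_data] object.
#' @export
read_lucid_data <- function(g_file = NULL, z_file = NULL, y_file = NULL,
                            wide_file = NULL, id_col = NULL) {
  if (!is.null(wide_file)) {
    df <- read_table_auto(wide_file)
    ids <- if (!is.null(id_col)) as.character(df[[id_col]]) else NULL
    if (!is.null(id_col)) df[[id_col]] <- NULL
    gcols <- grep("^G_", names(df))
    zcols <- grep("^Z_", names(df))
    ycols <- grep("^Y($|_)", names(df))
    if (!length(gcols) || !length(zcols) || length(ycols) != 1L)
      stop("wide file needs G_* columns, Z_* columns and a single Y column")
    G <- encode_exposures(df[gcols])
    Z <- as.matrix(df[zcols])
    Y <- df[[ycols]]
    return(lucid_data(G, Z, Y, row_ids = ids))
  }
  if (is.null(g_file) || is.null(z_file) || is.null(y_file))
    stop("provide either wide_file or all of g_file, z_file, y_file")
  G <- encode_exposures(read_table_auto(g_file))
  Zdf <- read_table_auto(z_file)
  if (!all(vapply(Zdf, is.numeric, TRUE) |
           vapply(Zdf, function(v) all(is.na(v)), TRUE)))
    stop("non-numeric cells in omics file ", z_file)
  Z <- as.matrix(Zdf)
  storage.mode(Z) <- "double"
  Ydf <- read_table_auto(y_file)
  if (ncol(Ydf) != 1L) stop("outcome file must have exactly one column")
  lucid_data(G, Z, Y = Ydf[[1L]])
}

#' Write a dataset back to CSV files
#'
#' Inverse of [read_lucid_data] for the three-file layout; masked omics
#' cells are written as `NA`, so a read/write/read round trip preserves
#' values and mask.
#'
#' @param data a [lucid_data].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths.
#' @export
write_lucid_data <- function(data, dir, prefix = "data") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("G", "Z", "Y"), ".csv"))
  utils::write.csv(as.data.frame(data$G), paths[1L], row.names = FALSE)
  Z <- data$Z
  Z[data$mask] <- NA
  utils::write.csv(as.data.frame(Z), paths[2L], row.names = FALSE)
  utils::write.csv(data.frame(Y = data$Y), paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Write the artifacts of a fit to a directory
#'
#' Emits `params.csv` (long table of all parameters),
#' `responsibilities.csv`, `imputed_Z.csv` (with per-cell mask columns),
#' `loglik_trace.csv` and `summary.json`.
#'
#' @param fit a `lucid_fit`.
#' @param dir output directory.
#' @param row_ids labels for the responsibility rows.
#' @return invisibly, the list of paths written.
#' @export
write_fit <- function(fit, dir, row_ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- fit$params
  ptab <- data.frame(parameter = scalar_param_names(p),
                     value = scalar_param_values(p))
  # covariances, flattened
  for (j in seq_len(p$K)) {
    S <- p$Sigma[[j]]
    idx <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
    ptab <- rbind(ptab, data.frame(
      parameter = sprintf("sigma%d_%d_%d", j, idx[, 1], idx[, 2]),
      value = S[idx]))
  }
  paths <- file.path(dir, c("params.csv", "responsibilities.csv",
                            "imputed_Z.csv", "loglik_trace.csv",
                            "summary.json"))
  utils::write.csv(ptab, paths[1L], row.names = FALSE)
  rdf <- as.data.frame(fit$r)
  names(rdf) <- paste0("cluster", seq_len(p$K))
  if (!is.null(row_ids)) rdf <- cbind(row_id = row_ids, rdf)
  utils::write.csv(rdf, paths[2L], row.names = FALSE)
  zdf <- as.data.frame(fit$Z_imputed)
  names(zdf) <- paste0("Z", seq_len(ncol(zdf)))
  zdf$listwise_missing <- seq_len(nrow(zdf)) %in% fit$partition$ic
  utils::write.csv(zdf, paths[3L], row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(fit$loglik_trace) - 1L,
                              loglik = fit$loglik_trace),
                   paths[4L], row.names = FALSE)
  summary <- list(K = p$K, cov_model = p$cov_model, n = fit$n,
                  loglik = fit$loglik, bic = fit$bic,
                  n_params = fit$n_params, converged = fit$converged,
                  iterations = length(fit$loglik_trace) - 1L,
                  partition = list(n_complete = fit$partition$n_a,
                                   n_sporadic = fit$partition$n_b,
                                   n_listwise = fit$partition$n_c),
                  seed = fit$seed, schema_version = 1L)
  jsonlite::write_json(summary, paths[5L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a fit configuration from JSON or YAML
#'
#' @param path a `.json`, `.yaml` or `.yml` file whose keys match the
#'   arguments of [fit_config].
#' @return a [fit_config].
#' @export
read_fit_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(fit_config))
  do.call(fit_config, cfg[intersect(names(cfg), known)])
}
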