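# Text readers/writers: phenotype tables (CSV/TSV), dense relationship
# matrices with optional ID headers, posterior summaries, run metadata.

na_tokens <- c("", "NA", "NaN", "nan")

# sniff comma vs whitespace delimitation from the first non-empty line
read_table_auto <- function(file, header = TRUE) {
  first <- readLines(file, n = 1)
  if (!length(first)) stop("'", file, "' is empty", call. = FALSE)
  if (grepl(",", first, fixed = TRUE))
    utils::read.csv(file, header = header, na.strings = na_tokens,
                    check.names = FALSE)
  else
    utils::read.table(file, header = header, na.strings = na_tokens,
                      check.names = FALSE)
}

#' Read a dense relationship matrix from a text file
#'
#' Accepts a square whitespace- or comma-delimited numeric matrix, optionally
#' carrying individual IDs as a header row and/or a leading ID column.
#'
#' @param file Path to the matrix file.
#' @return Numeric matrix; row/column names hold IDs when present.
#' @export
read_grm <- function(file) {
  if (!file.exists(file)) stop("GRM file '", file, "' does not exist",
                               call. = FALSE)
  raw <- read_table_auto(file, header = FALSE)
  ids <- NULL
  # header row of IDs: first row non-numeric
  first_row <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  if (any(is.na(first_row))) {
    ids <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
  }
  # leading ID column: first column non-numeric
  first_col <- suppressWarnings(as.numeric(raw[[1]]))
  if (any(is.na(first_col))) {
    row_ids <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (is.null(ids)) ids <- row_ids
    else ids <- ids[-1]  # header row included a label over the ID column
  }
  M <- matrix(suppressWarnings(as.numeric(as.matrix(raw))), nrow = nrow(raw))
  bad <- which(is.na(M), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric GRM entry at line ", bad[1, 1], ", column ", bad[1, 2],
         call. = FALSE)
  if (nrow(M) != ncol(M))
    stop("GRM is not square: ", nrow(M), " x ", ncol(M), call. = FALSE)
  asym <- which(abs(M - t(M)) > 1e-8, arr.ind = TRUE)
  if (nrow(asym))
    stop("GRM is asymmetric at entry (", asym[1, 1], ", ", asym[1, 2], ")",
         call. = FALSE)
  if (!is.null(ids)) dimnames(M) <- list(ids, ids)
  M
}

#' Read and align a phenotype table and relationship matrix
#'
#' Reads a delimited phenotype table (header required) and a dense GRM text
#' file, drops individuals with a missing phenotype or covariate (logging the
#' count), aligns on IDs when both files carry them, and returns a validated
#' [gprebe_data()].
#'
#' @param phenotype_file Delimited table with at least the phenotype and
#'   covariate columns; missing values may be empty, `NA` or `NaN`.
#' @param covariate_column Name of the covariate column.
#' @param grm_file Dense relationship-matrix file (see [read_grm()]).
#' @param phenotype_column Name of the phenotype column (default
#'   `"phenotype"`).
#' @param id_column Optional name of an ID column used to align with GRM IDs.
#' @param fixed_columns Optional character vector of fixed-effect columns;
#'   an intercept is always included.
#' @return A [gprebe_data()] object.
#' @export
read_dataset <- function(phenotype_file, covariate_column, grm_file,
                         phenotype_column = "phenotype", id_column = NULL,
                         fixed_columns = NULL) {
  if (!file.exists(phenotype_file))
    stop("phenotype file '", phenotype_file, "' does not exist",
         call. = FALSE)
  tab <- read_table_auto(phenotype_file)
  need <- c(phenotype_column, covariate_column, id_column, fixed_columns)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- suppressWarnings(as.numeric(tab[[phenotype_column]]))
  t <- suppressWarnings(as.numeric(tab[[covariate_column]]))
  keep <- !is.na(y) & !is.na(t)
  if (length(fixed_columns))
    for (fc in fixed_columns)
      keep <- keep & !is.na(suppressWarnings(as.numeric(tab[[fc]])))
  dropped <- sum(!keep)
  if (dropped > 0)
    message("dropped ", dropped,
            " individual(s) with missing phenotype/covariate values")
  G <- read_grm(grm_file)
  idx <- which(keep)
  if (!is.null(id_column) && !is.null(rownames(G))) {
    ids <- as.character(tab[[id_column]])[idx]
    pos <- match(ids, rownames(G))
    if (anyNA(pos))
      stop("ID(s) missing from the GRM: ",
           paste(utils::head(ids[is.na(pos)], 3), collapse = ", "),
           call. = FALSE)
    G <- G[pos, pos]
  } else if (nrow(G) != nrow(tab)) {
    stop("GRM dimension (", nrow(G), ") does not match the phenotype table (",
         nrow(tab), " rows) and no IDs are available for alignment",
         call. = FALSE)
  } else {
    G <- G[idx, idx]
  }
  X <- if (length(fixed_columns))
    cbind(1, as.matrix(sapply(fixed_columns,
                              function(fc) as.numeric(tab[[fc]])[idx])))
  else NULL
  gprebe_data(y[idx], t[idx], G, X)
}

#' Write a simulated replicate as CLI-readable files
#'
#' Writes `<prefix>_phenotypes.csv` (id, phenotype, covariate),
#' `<prefix>_grm.txt` (dense matrix with ID header row) and
#' `<prefix>_truth.csv` (true variance curves at covariate points).
#'
#' @param rep A `sim_replicate`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_replicate <- function(rep, prefix) {
  n <- length(rep$y)
  ids <- paste0("id", seq_len(n))
  ph <- data.frame(id = ids, phenotype = rep$y, covariate = rep$t)
  f1 <- paste0(prefix, "_phenotypes.csv")
  utils::write.csv(ph, f1, row.names = FALSE, quote = FALSE)
  f2 <- paste0(prefix, "_grm.txt")
  con <- file(f2, "w")
  writeLines(paste(ids, collapse = " "), con)
  utils::write.table(format(rep$G, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  f3 <- paste0(prefix, "_truth.csv")
  utils::write.csv(data.frame(id = ids, covariate = rep$t,
                              sigmaG2_true = rep$sigma_g2,
                              sigmaE2_true = rep$sigma_e2),
                   f3, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3))
}

#' Write a fit's posterior summary, chain and metadata
#'
#' Writes `<prefix>_summary.csv` (10 columns: grid point plus mean/lo/hi of
#' the residual variance, genetic variance and heritability curves),
#' `<prefix>_chain.csv` (kept post-burn-in states, columns `sE_1..sE_N,
#' sG_1..sG_N` on the scaled log-variance scale) and `<prefix>_meta.json`
#' (resolved configuration, seed, scale factor, acceptance rate, package
#' version).
#'
#' @param fit A [gprebe()] fit.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_summary <- function(fit, prefix) {
  f1 <- paste0(prefix, "_summary.csv")
  utils::write.csv(format(fit$summary, digits = 12, trim = TRUE),
                   f1, row.names = FALSE, quote = FALSE)
  N <- length(fit$grid)
  ch <- as.data.frame(fit$chain)
  names(ch) <- c(paste0("sE_", seq_len(N)), paste0("sG_", seq_len(N)))
  f2 <- paste0(prefix, "_chain.csv")
  utils::write.csv(ch, f2, row.names = FALSE, quote = FALSE)
  f3 <- paste0(prefix, "_meta.json")
  meta <- list(config = fit$config, scale_factor = fit$scale_factor,
               accept_rate = fit$accept_rate, step_size = fit$step_size,
               map_converged = fit$map$converged,
               n = length(fit$data$y),
               package_version = as.character(utils::packageVersion("gprebe")))
  jsonlite::write_json(meta, f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}

#' Re-read a written posterior summary
#'
#' @param file Path to a `*_summary.csv` written by [write_summary()].
#' @return Data frame in the [summarize_chain()] layout.
#' @export
read_summary <- function(file) {
  out <- utils::read.csv(file)
  expected <- c("t", "sigmaE2_mean", "sigmaE2_lo", "sigmaE2_hi",
                "sigmaG2_mean", "sigmaG2_lo", "sigmaG2_hi",
                "h2_mean", "h2_lo", "h2_hi")
  if (!identical(names(out), expected))
    stop("'", file, "' is not a gprebe summary file", call. = FALSE)
  out
}
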