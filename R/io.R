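#' Read a per-gene DNM count table
#'
#' Reads the tab-separated gene table with header
#' `gene_id  mu  y1  [y2]` and validates it: positive mutabilities,
#' integer counts, unique gene identifiers. Malformed rows are rejected
#' with the offending line numbers rather than coerced.
#'
#' @param path Path to the TSV file.
#' @return A validated gene table data frame.
#' @export
read_gene_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- c("gene_id", "mu", "y1")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         "; expected header gene_id\tmu\ty1\t[y2]")
  }
  num_cols <- intersect(c("mu", "y1", "y2"), names(raw))
  out <- data.frame(gene_id = raw$gene_id, stringsAsFactors = FALSE)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- is.na(v) & !(raw[[cc]] %in% c("NA", ""))
    if (any(bad)) {
      stop(path, ": non-numeric value in column ", cc, " at data line(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    out[[cc]] <- v
  }
  dup <- which(duplicated(out$gene_id))
  if (length(dup)) {
    stop(path, ": duplicate gene_id at data line(s) ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  validate_gene_table(out)
}

#' Write a gene table as TSV
#'
#' @param table Gene table data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(table, path) {
  cols <- intersect(c("gene_id", "mu", "y1", "y2"), names(table))
  utils::write.table(table[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant-level annotation table
#'
#' TSV with required columns `gene_id` and `variant_id` plus numeric
#' annotation columns; one row per observed DNM.
#'
#' @param path Path to the TSV file.
#' @return Data frame with annotation columns as numeric.
#' @export
read_variant_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("gene_id", "variant_id")
  if (!all(required %in% names(raw))) {
    stop(path, ": variant table needs columns gene_id and variant_id")
  }
  for (cc in setdiff(names(raw), required)) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- is.na(v) & !is.na(raw[[cc]]) & raw[[cc]] != "NA"
    if (any(bad)) {
      stop(path, ": non-numeric annotation value in column ", cc,
           " at data line(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    raw[[cc]] <- v
  }
  raw
}

#' Serialize a fit to JSON
#'
#' Writes `pi`, the beta vectors, the log-likelihood trace, convergence
#' flag and iteration count as JSON; the posterior goes to a companion TSV
#' keyed by `gene_id` when `posterior_path` is given.
#'
#' @param fit A `dnm_fit` object.
#' @param path Output JSON path.
#' @param posterior_path Optional TSV path for the posterior matrix.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, posterior_path = NULL) {
  stopifnot(inherits(fit, "dnm_fit"))
  payload <- list(pi = as.list(fit$params$pi),
                  beta1 = fit$params$beta1,
                  beta2 = fit$params$beta2,
                  loglik_trace = fit$loglik_trace,
                  converged = fit$converged,
                  n_iter = fit$n_iter)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(posterior_path)) {
    post <- data.frame(gene_id = fit$gene_id,
                       as.data.frame(fit$posterior, optional = TRUE),
                       check.names = FALSE)
    utils::write.table(post, posterior_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write an inference result table with its JSON sidecar
#'
#' The TSV holds the per-gene Jlfdr, running-mean Fdr, and significance
#' flags; the sidecar records the nominal level `q` and package version.
#'
#' @param test Result table from [run_inference()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(test, path) {
  utils::write.table(test, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(q = attr(test, "q"),
         n_genes = nrow(test),
         package = "dnmjoint",
         version = as.character(utils::packageVersion("dnmjoint"))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a simulation configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [sim_config()] arguments and
#' builds the validated configuration; unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(sim_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(path, ": unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  for (k in c("pi", "beta1", "beta2", "observed")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.numeric(unlist(raw[[k]]))
  }
  do.call(sim_config, raw)
}
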