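#' Collapse variant-level annotations to gene level
#'
#' Each row of `variants` is one observed DNM with its annotation values;
#' the gene-level score for an annotation is the sum of its (optionally
#' centered) values over the gene's DNMs. A first-order expansion of the
#' likelihood ratio of a gene's counts under risk versus null shows that,
#' for small variant-level effects and centered annotations, this sum is the
#' sufficient gene-level feature, which motivates sum-collapsing. Centering
#' subtracts the cohort-wide mean of the annotation over all observed DNMs;
#' binary flags (e.g. LoF indicators) are left uncentered so their collapsed
#' value is the gene's flagged-DNM count. Genes with no DNMs score 0.
#' Missing annotation values are imputed with the annotation's DNM-wide
#' mean, with a message giving the tally.
#'
#' @param variants Data frame with columns `gene_id`, `variant_id` and one
#'   numeric column per annotation.
#' @param genes Character vector: the full gene universe (including genes
#'   with zero DNMs).
#' @param center Logical: center continuous annotations before summing
#'   (default `TRUE`).
#' @param binary_features Character vector naming annotation columns to
#'   treat as binary flags (never centered).
#' @return Data frame with `gene_id` and one collapsed column per
#'   annotation, one row per gene in `genes` (input order).
#' @export
collapse_to_gene <- function(variants, genes, center = TRUE,
                             binary_features = character()) {
  stopifnot(is.character(genes), length(genes) > 0L)
  required <- c("gene_id", "variant_id")
  if (!all(required %in% names(variants))) {
    stop("variant table needs columns gene_id and variant_id")
  }
  unknown <- setdiff(unique(variants$gene_id), genes)
  if (length(unknown)) {
    stop("variant rows map to gene(s) outside the gene universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  anno_cols <- setdiff(names(variants), required)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  idx <- match(variants$gene_id, genes)
  for (a in anno_cols) {
    v <- as.numeric(variants[[a]])
    miss <- is.na(v)
    if (any(miss)) {
      v[miss] <- mean(v[!miss])
      message("annotation '", a, "': imputed ", sum(miss),
              " missing value(s) with the DNM-wide mean")
    }
    if (center && !(a %in% binary_features)) v <- v - mean(v)
    out[[a]] <- as.vector(tapply(v, factor(idx, levels = seq_along(genes)),
                                 sum, default = 0))
  }
  out
}

#' Standardize gene-level features
#'
#' Scales every feature column to mean 0 and standard deviation 1 across
#' genes, using the population (1/n) standard deviation. Constant columns
#' carry no information and are dropped with a warning; if every column is
#' constant the result has no feature columns (the downstream design is
#' then intercept-only).
#'
#' @param features Data frame with `gene_id` plus numeric feature columns,
#'   or a plain numeric matrix/data frame of features.
#' @return Same shape with each retained column standardized.
#' @export
standardize_features <- function(features) {
  has_id <- is.data.frame(features) && "gene_id" %in% names(features)
  id <- if (has_id) features$gene_id else NULL
  x <- if (has_id) features[setdiff(names(features), "gene_id")] else as.data.frame(features)
  if (nrow(x) < 2L) stop("standardization needs at least 2 genes")
  keep <- list()
  for (a in names(x)) {
    v <- as.numeric(x[[a]])
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) {
      warning("dropping constant feature '", a, "'", call. = FALSE)
      next
    }
    keep[[a]] <- (v - mean(v)) / s
  }
  if (!length(keep)) {
    warning("all features constant; returning an empty feature set",
            call. = FALSE)
  }
  out <- if (length(keep)) as.data.frame(keep, optional = TRUE) else
    data.frame(row.names = seq_len(nrow(x)))
  if (has_id) out <- cbind(data.frame(gene_id = id, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Stage-1 feature selection: correlation pruning
#'
#' Greedy scan in input column order: a feature is dropped when its Pearson
#' correlation with any already-kept feature exceeds `threshold`. By default
#' the signed correlation is compared (so strong negative correlation does
#' not trigger a drop); `absolute = TRUE` compares `|r|` instead. The first
#' of a correlated pair — in column order — is the one kept.
#'
#' @param features Data frame (optionally with `gene_id`) or matrix of
#'   gene-level features.
#' @param threshold Correlation cutoff in `(0, 1)`; default 0.7.
#' @param absolute Compare `|r|` rather than signed `r`.
#' @return A list of class `feature_selection_report`: `kept` (names in
#'   order), `dropped_pairs` (data frame `kept`, `dropped`, `r`), plus the
#'   pruned feature table in `$features`.
#' @export
prune_correlated <- function(features, threshold = 0.7, absolute = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  has_id <- is.data.frame(features) && "gene_id" %in% names(features)
  x <- if (has_id) features[setdiff(names(features), "gene_id")] else as.data.frame(features)
  if (nrow(x) < 2L) stop("correlation is undefined for fewer than 2 genes")
  kept <- character(0)
  drops <- list()
  for (a in names(x)) {
    clash <- NULL
    for (b in kept) {
      r <- stats::cor(x[[a]], x[[b]])
      rr <- if (absolute) abs(r) else r
      if (is.finite(rr) && rr > threshold) {
        clash <- list(kept = b, dropped = a, r = r)
        break
      }
    }
    if (is.null(clash)) kept <- c(kept, a) else drops[[length(drops) + 1L]] <- clash
  }
  dropped_pairs <- if (length(drops)) {
    do.call(rbind, lapply(drops, as.data.frame, stringsAsFactors = FALSE))
  } else {
    data.frame(kept = character(0), dropped = character(0), r = numeric(0))
  }
  out_feat <- x[kept]
  if (has_id) out_feat <- cbind(features["gene_id"], out_feat)
  structure(list(kept = kept, dropped_pairs = dropped_pairs,
                 threshold = threshold, absolute = absolute,
                 features = out_feat),
            class = "feature_selection_report")
}

#' Stage-2 feature selection: effect-size screening and refit
#'
#' Fits the single-trait annotation model on the supplied design, retains
#' the non-intercept features whose fitted effect exceeds `cutoff` in
#' absolute value, and refits the model with the retained set (features are
#' screened per trait by single-trait analysis; multi-trait designs are then
#' assembled from each trait's selected features). If nothing survives the
#' screen the refit is intercept-only.
#'
#' @param table Single-trait gene table (columns `gene_id`, `mu`, `y1`).
#' @param cohorts Cohort sizes; only `n1` is used.
#' @param design Design matrix from [make_design()] with named feature
#'   columns.
#' @param options A [fit_options()] list.
#' @param cutoff Absolute effect-size threshold; default 0.01.
#' @return A list of class `feature_selection_report`: `kept` (surviving
#'   feature names), `effect_sizes` (named vector from the screening fit),
#'   `fit` (the refit on the selected features), `design` (the final design
#'   matrix).
#' @export
select_by_effect_size <- function(table, cohorts, design,
                                  options = fit_options(), cutoff = 0.01) {
  stopifnot(ncol(design) >= 1L)
  screen_fit <- fit_single(table, cohorts, design, options)
  if (!screen_fit$converged) {
    stop("screening fit did not converge; feature selection aborted")
  }
  beta <- screen_fit$params$beta1
  feat_names <- colnames(design)[-1L]
  effects <- if (length(feat_names)) stats::setNames(beta[-1L], feat_names) else
    stats::setNames(numeric(0), character(0))
  kept <- feat_names[abs(effects) > cutoff]
  final_design <- if (length(kept)) {
    design[, c("(Intercept)", kept), drop = FALSE]
  } else {
    make_design(m = nrow(design))
  }
  final_fit <- if (length(kept) == length(feat_names)) screen_fit else
    fit_single(table, cohorts, final_design, options)
  structure(list(kept = kept, effect_sizes = effects, cutoff = cutoff,
                 fit = final_fit, design = final_design),
            class = "feature_selection_report")
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat("Feature selection report\n")
  if (!is.null(x$threshold)) {
    cat("  correlation pruning at r >", x$threshold,
        if (isTRUE(x$absolute)) "(absolute)" else "(signed)", "\n")
    cat("  kept:", if (length(x$kept)) paste(x$kept, collapse = ", ") else "(none)", "\n")
    if (nrow(x$dropped_pairs)) {
      for (i in seq_len(nrow(x$dropped_pairs))) {
        cat(sprintf("  dropped %s (r = %.3f with %s)\n",
                    x$dropped_pairs$dropped[i], x$dropped_pairs$r[i],
                    x$dropped_pairs$kept[i]))
      }
    }
  } else {
    cat("  effect-size screen at |beta| >", x$cutoff, "\n")
    cat("  kept:", if (length(x$kept)) paste(x$kept, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}
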