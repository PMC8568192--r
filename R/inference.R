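#' Joint local false discovery rate per gene
#'
#' The Jlfdr for a trait is the posterior probability that the gene is null
#' for that trait given both traits' counts: for trait 1,
#' `Pr(Z_00 + Z_01 = 1 | Y_1, Y_2)`, i.e. the sum of the `"00"` and `"01"`
#' posterior columns (for trait 2, `"00"` + `"10"`). In single-trait mode it
#' is the posterior probability of `Z = 0`.
#'
#' @param posterior Posterior matrix from [e_step()] or a fit.
#' @param trait 1 or 2.
#' @return Numeric vector of per-gene Jlfdr values in `[0, 1]`.
#' @export
jlfdr <- function(posterior, trait = 1L) {
  k <- if (ncol(posterior) == 2L) 1L else 2L
  null_cols <- setdiff(class_labels(k), risk_classes(trait, k))
  v <- unname(rowSums(posterior[, null_cols, drop = FALSE]))
  pmin(pmax(v, 0), 1)  # guard against roundoff just outside [0, 1]
}

#' Global-FDR threshold on local fdr values
#'
#' Sorts the Jlfdr values ascending, forms running means
#' `Fdr(a) = a^-1 sum_{b<=a} Jlfdr_(b)`, finds the largest rank `c` whose
#' running mean is at or below `q`, and rejects every gene whose Jlfdr is at
#' or below the `c`-th sorted value (ties included). When even the smallest
#' value exceeds `q` nothing is rejected. The running mean over the rejected
#' set estimates the realized global false discovery rate.
#'
#' @param jlfdr_values Numeric vector of per-gene Jlfdr values in `[0, 1]`.
#' @param q Nominal global Fdr level in `(0, 1)`.
#' @return A list: `threshold` (the Jlfdr cutoff `t(q)`, `-Inf` when nothing
#'   is rejected), `reject` (logical, in input order), `fdr` (running-mean
#'   Fdr at each gene's rank, in input order), `n_reject`.
#' @export
fdr_threshold <- function(jlfdr_values, q = 0.05) {
  if (length(jlfdr_values) == 0L) stop("empty Jlfdr vector")
  if (any(!is.finite(jlfdr_values)) ||
      any(jlfdr_values < 0) || any(jlfdr_values > 1)) {
    stop("Jlfdr values must lie in [0, 1]")
  }
  if (length(q) != 1L || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ord <- order(jlfdr_values)
  s <- jlfdr_values[ord]
  cm <- cumsum(s) / seq_along(s)
  ok <- which(cm <= q)
  threshold <- if (length(ok)) s[max(ok)] else -Inf
  fdr <- numeric(length(s))
  fdr[ord] <- cm
  reject <- jlfdr_values <= threshold
  list(threshold = threshold, reject = reject, fdr = fdr,
       n_reject = sum(reject))
}

#' Identify risk genes from a fitted model
#'
#' Computes per-trait Jlfdr from the fitted posterior, applies the
#' running-mean global-FDR threshold at level `q` for each trait, and
#' returns the per-gene result table sorted by trait-1 Jlfdr.
#'
#' @param fit A `dnm_fit` from [fit_multi()] or [fit_single()].
#' @param q Nominal global Fdr level (default 0.05).
#' @return A data frame with `gene_id`, counts, `mu`, and per-trait columns
#'   `jlfdr_t*`, `fdr_t*`, `sig_t*`; attribute `"q"` records the level.
#' @export
run_inference <- function(fit, q = 0.05) {
  stopifnot(inherits(fit, "dnm_fit"))
  out <- data.frame(gene_id = fit$gene_id,
                    y1 = fit$table$y1,
                    stringsAsFactors = FALSE)
  if (fit$n_traits == 2L) out$y2 <- fit$table$y2
  out$mu <- fit$table$mu
  for (tr in seq_len(fit$n_traits)) {
    j <- jlfdr(fit$posterior, tr)
    th <- fdr_threshold(j, q)
    out[[paste0("jlfdr_t", tr)]] <- j
    out[[paste0("fdr_t", tr)]] <- th$fdr
    out[[paste0("sig_t", tr)]] <- th$reject
  }
  out <- out[order(out$jlfdr_t1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q") <- q
  out
}
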