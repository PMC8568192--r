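# Latent-class labels in fixed on-disk order. Two-trait classes are
# (00, 10, 01, 11): first digit = trait-1 risk, second digit = trait-2 risk.
class_labels <- function(n_traits) {
  if (n_traits == 1L) c("0", "1") else c("00", "10", "01", "11")
}

# Columns of the posterior that carry risk for a given trait.
risk_classes <- function(trait, n_traits) {
  if (n_traits == 1L) {
    if (trait != 1L) stop("single-trait posterior has no trait ", trait)
    "1"
  } else if (trait == 1L) {
    c("10", "11")
  } else if (trait == 2L) {
    c("01", "11")
  } else {
    stop("trait must be 1 or 2")
  }
}

#' Expected de novo mutation count under the Poisson model
#'
#' The expected DNM count for a gene in a trio cohort is `2 * n * mu * gamma`:
#' `2 * n * mu` new mutations expected among `n` probands (two haploid
#' genomes each) at per-gene mutability `mu`, inflated by the relative risk
#' `gamma` if the gene is a risk gene (`gamma = 1` gives the null mean).
#'
#' @param n Cohort size (number of trios), at least 1.
#' @param mu Per-gene mutability for the analyzed mutation class
#'   (probability per haploid genome per generation); must be positive.
#' @param gamma Relative risk, positive; defaults to 1 (null).
#' @return The Poisson mean `2 * n * mu * gamma` (vectorized over arguments).
#' @examples
#' expected_count(5000, 1e-5)       # 0.1
#' expected_count(5000, 1e-5, 20)   # 2
#' @export
expected_count <- function(n, mu, gamma = 1) {
  if (any(n < 1)) stop("cohort size n must be >= 1")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mutability mu must be positive and finite")
  if (any(!is.finite(gamma)) || any(gamma <= 0)) stop("relative risk gamma must be positive and finite")
  2 * n * mu * gamma
}

#' Relative risk from annotations through the exponential link
#'
#' Computes `gamma = exp(x' beta)` for one gene, where `x` is the gene's
#' annotation row (first entry the intercept 1) and `beta` the effect-size
#' vector. With an intercept-only design every gene gets `exp(beta0)`.
#'
#' @param x_row Numeric annotation vector including the leading intercept 1.
#' @param beta Numeric effect-size vector of the same length.
#' @return The positive scalar relative risk.
#' @examples
#' gene_relative_risk(c(1, 0, 0), c(3, 0.1, 0.1))  # exp(3)
#' @export
gene_relative_risk <- function(x_row, beta) {
  if (length(x_row) != length(beta)) {
    stop("annotation row has length ", length(x_row),
         " but beta has length ", length(beta))
  }
  if (any(!is.finite(x_row)) || any(!is.finite(beta))) {
    stop("non-finite values in annotation row or beta")
  }
  exp(sum(x_row * beta))
}

#' Log-likelihood of a gene's counts under one latent class
#'
#' Log of `Pr(Y1, Y2 | Z = class)`: the sum of two Poisson log densities
#' with means `2*N1*mu*g1` and `2*N2*mu*g2`, where `g1` is `gamma1` when the
#' class carries trait-1 risk (classes `"10"`, `"11"`) and 1 otherwise, and
#' likewise `g2` for trait-2 risk (classes `"01"`, `"11"`). In single-trait
#' mode (`y2 = NULL`) the labels are `"0"` and `"1"` and only the first
#' Poisson term is used.
#'
#' @param y1,y2 Observed DNM counts (non-negative integers); `y2 = NULL` for
#'   single-trait mode.
#' @param n1,n2 Cohort sizes (trios).
#' @param mu Gene mutability.
#' @param gamma1,gamma2 Relative risks for each trait.
#' @param class_label One of `"00"`, `"10"`, `"01"`, `"11"` (two traits) or
#'   `"0"`, `"1"` (one trait).
#' @return Log-probability (vectorized over genes).
#' @export
class_loglik <- function(y1, y2 = NULL, n1, n2 = NULL, mu,
                         gamma1 = 1, gamma2 = 1, class_label) {
  single <- is.null(y2)
  valid <- if (single) c("0", "1") else c("00", "10", "01", "11")
  if (length(class_label) != 1L || !class_label %in% valid) {
    stop("invalid class label '", paste(class_label, collapse = ","),
         "'; expected one of ", paste(valid, collapse = ", "))
  }
  g1 <- if (substr(class_label, 1L, 1L) == "1") gamma1 else 1
  ll <- stats::dpois(y1, expected_count(n1, mu, g1), log = TRUE)
  if (!single) {
    g2 <- if (substr(class_label, 2L, 2L) == "1") gamma2 else 1
    ll <- ll + stats::dpois(y2, expected_count(n2, mu, g2), log = TRUE)
  }
  ll
}

#' Construct an annotation design matrix
#'
#' Prepends the intercept column of ones to a gene-by-feature table. With
#' `features = NULL` returns the intercept-only design, under which the
#' exponential link degenerates to a single shared relative risk.
#'
#' @param features Numeric matrix or data frame of gene-level features
#'   (rows = genes), or `NULL` for intercept-only.
#' @param m Number of genes; required when `features` is `NULL`.
#' @return Numeric matrix with first column `(Intercept)` identically 1.
#' @export
make_design <- function(features = NULL, m = NULL) {
  if (is.null(features)) {
    if (is.null(m)) stop("m (number of genes) required for an intercept-only design")
    return(matrix(1, nrow = m, ncol = 1L,
                  dimnames = list(NULL, "(Intercept)")))
  }
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  if (any(!is.finite(x))) stop("non-finite values in feature matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  cbind(`(Intercept)` = 1, x)
}

# TRUE when a design matrix is the degenerate intercept-only case.
is_intercept_only <- function(design) {
  ncol(design) == 1L && all(design[, 1L] == 1)
}

#' Bundle mixture parameters
#'
#' Collects the latent-class proportions `pi` and the per-trait annotation
#' effect vectors into a validated parameter object. Two-trait `pi` is
#' ordered `(00, 10, 01, 11)`; single-trait `pi` is `(0, 1)`.
#'
#' @param pi Probability vector of length 4 (two traits) or 2 (one trait).
#' @param beta1 Effect vector for trait 1 (first entry the intercept).
#' @param beta2 Effect vector for trait 2, or `NULL` in single-trait mode.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(pi, beta1, beta2 = NULL) {
  pi <- as.numeric(pi)
  if (!length(pi) %in% c(2L, 4L)) stop("pi must have length 2 or 4")
  if (any(pi < 0)) stop("pi must be non-negative")
  if (abs(sum(pi) - 1) > 1e-10) stop("pi must sum to 1 (got ", sum(pi), ")")
  if (length(pi) == 4L && is.null(beta2)) stop("two-trait pi requires beta2")
  if (length(pi) == 2L && !is.null(beta2)) stop("single-trait pi admits no beta2")
  if (any(!is.finite(beta1)) || (!is.null(beta2) && any(!is.finite(beta2)))) {
    stop("beta vectors must be finite")
  }
  names(pi) <- class_labels(if (length(pi) == 4L) 2L else 1L)
  structure(list(pi = pi, beta1 = as.numeric(beta1),
                 beta2 = if (is.null(beta2)) NULL else as.numeric(beta2)),
            class = "mixture_params")
}

n_traits_of <- function(params) if (length(params$pi) == 4L) 2L else 1L

#' @export
print.mixture_params <- function(x, ...) {
  cat("Mixture parameters (", n_traits_of(x), " trait",
      if (n_traits_of(x) > 1L) "s", ")\n", sep = "")
  cat("  pi:   ", paste(sprintf("%s=%.4g", names(x$pi), x$pi), collapse = "  "), "\n")
  cat("  beta1:", paste(sprintf("%.4g", x$beta1), collapse = " "), "\n")
  if (!is.null(x$beta2)) {
    cat("  beta2:", paste(sprintf("%.4g", x$beta2), collapse = " "), "\n")
  }
  invisible(x)
}

# Validate a gene table: required columns, positive mu, integer counts,
# unique gene ids. Returns the table with the trait count as an attribute.
#' Validate a per-gene DNM count table
#'
#' Checks the invariants of the gene table: columns `gene_id`, `mu`, `y1`
#' (and optionally `y2`); `mu` strictly positive and finite; counts
#' non-negative integers; `gene_id` unique. Violations raise errors naming
#' the offending genes.
#'
#' @param table Data frame with columns `gene_id`, `mu`, `y1`, optionally `y2`.
#' @return The validated table (invisibly usable), with column `y2` implying
#'   two-trait mode.
#' @export
validate_gene_table <- function(table) {
  required <- c("gene_id", "mu", "y1")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("gene table is empty")
  dup <- unique(table$gene_id[duplicated(table$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad_mu <- !is.finite(table$mu) | table$mu <= 0
  if (any(bad_mu)) {
    stop("non-positive or missing mutability for gene(s): ",
         paste(utils::head(table$gene_id[bad_mu], 5L), collapse = ", "))
  }
  count_cols <- intersect(c("y1", "y2"), names(table))
  for (cc in count_cols) {
    y <- table[[cc]]
    bad <- !is.finite(y) | y < 0 | y != round(y)
    if (any(bad)) {
      stop("column ", cc, " must hold non-negative integers; offending gene(s): ",
           paste(utils::head(table$gene_id[bad], 5L), collapse = ", "))
    }
  }
  table
}

#' Describe the case cohorts
#'
#' @param n1 Trio count of cohort 1 (positive integer).
#' @param n2 Trio count of cohort 2, or `NULL` in single-trait mode.
#' @return A list with elements `n1` and (optionally) `n2`.
#' @export
cohort_info <- function(n1, n2 = NULL) {
  chk <- function(n, nm) {
    if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
      stop(nm, " must be a positive integer (trio count)")
    }
    as.integer(n)
  }
  out <- list(n1 = chk(n1, "n1"))
  if (!is.null(n2)) out$n2 <- chk(n2, "n2")
  out
}

# M x L matrix of log Pr(Y_i | Z_i = l) for all genes and classes.
# designs: list of per-trait design matrices (with intercept column).
class_logmat <- function(table, cohorts, designs, params) {
  mu <- table$mu
  lam1 <- 2 * cohorts$n1 * mu
  g1 <- exp(as.vector(designs[[1L]] %*% params$beta1))
  a1 <- stats::dpois(table$y1, lam1, log = TRUE)
  b1 <- stats::dpois(table$y1, lam1 * g1, log = TRUE)
  if (n_traits_of(params) == 1L) {
    out <- cbind(a1, b1)
  } else {
    if (is.null(table$y2) || is.null(cohorts$n2)) {
      stop("two-trait parameters require a y2 column and cohort size n2")
    }
    lam2 <- 2 * cohorts$n2 * mu
    g2 <- exp(as.vector(designs[[2L]] %*% params$beta2))
    a2 <- stats::dpois(table$y2, lam2, log = TRUE)
    b2 <- stats::dpois(table$y2, lam2 * g2, log = TRUE)
    out <- cbind(a1 + a2, b1 + a2, a1 + b2, b1 + b2)
  }
  colnames(out) <- class_labels(n_traits_of(params))
  out
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(lp) {
  m <- do.call(pmax, as.data.frame(lp))
  m + log(rowSums(exp(lp - m)))
}

#' Marginal log-likelihood of the mixture model
#'
#' Total observed-data log-likelihood
#' `sum_i log sum_l pi_l Pr(Y_i | Z_i = l)`, accumulated in log space with a
#' log-sum-exp over latent classes.
#'
#' @param table Validated gene table (see [validate_gene_table()]).
#' @param cohorts Cohort sizes from [cohort_info()].
#' @param designs List of per-trait design matrices, row-aligned with
#'   `table` (one matrix in single-trait mode).
#' @param params A [mixture_params()] object.
#' @return The scalar log-likelihood.
#' @export
marginal_loglik <- function(table, cohorts, designs, params) {
  if (!inherits(params, "mixture_params")) {
    params <- mixture_params(params$pi, params$beta1, params$beta2)
  }
  lp <- class_logmat(table, cohorts, designs, params)
  lp <- sweep(lp, 2L, log(params$pi), "+")
  sum(row_logsumexp(lp))
}
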