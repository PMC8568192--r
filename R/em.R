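#' Options controlling the EM fit
#'
#' @param max_em_iter Maximum EM iterations.
#' @param loglik_rel_tol Stop when the relative increase of the marginal
#'   log-likelihood falls below this value.
#' @param newton_max_iter Maximum damped Newton steps per M-step when a
#'   design has annotation columns.
#' @param newton_grad_tol Stop the inner Newton loop when the gradient
#'   infinity-norm falls below this value.
#' @param ridge Relative ridge added to the Hessian when it is numerically
#'   singular.
#' @param init_pi `"default"` for the built-in interior start
#'   (`(0.90, 0.04, 0.04, 0.02)` for two traits, `(0.9, 0.1)` for one), or a
#'   probability vector.
#' @param init_beta_intercept `"moment"` to start each trait's intercept at
#'   `log(max(1.5, sum(Y) / sum(2 N mu)))` (an interior start with relative
#'   risk above 1, matching the model's assumption), or a numeric value.
#' @param seed Integer seed used only if a randomized restart is requested
#'   elsewhere; the default fit is deterministic.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_em_iter = 5000L,
                        loglik_rel_tol = 1e-8,
                        newton_max_iter = 100L,
                        newton_grad_tol = 1e-8,
                        ridge = 1e-8,
                        init_pi = "default",
                        init_beta_intercept = "moment",
                        seed = 1L) {
  stopifnot(max_em_iter >= 1L, newton_max_iter >= 1L,
            loglik_rel_tol > 0, newton_grad_tol > 0, ridge >= 0)
  structure(list(max_em_iter = as.integer(max_em_iter),
                 loglik_rel_tol = loglik_rel_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 newton_grad_tol = newton_grad_tol,
                 ridge = ridge,
                 init_pi = init_pi,
                 init_beta_intercept = init_beta_intercept,
                 seed = as.integer(seed)),
            class = "fit_options")
}

#' E-step: posterior class probabilities
#'
#' For each gene computes
#' `Pr(Z_i = l | Y_i) = pi_l Pr(Y_i | l) / sum_l' pi_l' Pr(Y_i | l')`,
#' normalized in log space. The attribute `"loglik"` carries the marginal
#' log-likelihood at the supplied parameters (the log of the normalizer,
#' summed over genes), so EM gets the trace for free.
#'
#' @inheritParams marginal_loglik
#' @return An M x L posterior matrix whose rows sum to 1, with attribute
#'   `"loglik"`.
#' @export
e_step <- function(table, cohorts, designs, params) {
  lp <- class_logmat(table, cohorts, designs, params)
  lp <- sweep(lp, 2L, log(params$pi), "+")
  m <- do.call(pmax, as.data.frame(lp))
  bad <- !is.finite(m)
  if (any(bad)) {
    stop("zero likelihood in every class for gene ",
         table$gene_id[which(bad)[1L]])
  }
  w <- exp(lp - m)
  s <- rowSums(w)
  post <- w / s
  attr(post, "loglik") <- sum(m + log(s))
  post
}

#' M-step update of the class proportions
#'
#' The maximizer of the expected complete-data log-likelihood in `pi` is the
#' column mean of the posterior: `pi_l = sum_i Z_il / M`.
#'
#' @param posterior Posterior matrix from [e_step()].
#' @return A probability vector over classes.
#' @export
m_step_pi <- function(posterior) {
  if (is.null(dim(posterior)) || nrow(posterior) == 0L) {
    stop("posterior matrix is empty")
  }
  colMeans(posterior)
}

# Posterior weight that gene i carries trait-`trait` risk.
trait_weights <- function(posterior, trait) {
  k <- if (ncol(posterior) == 2L) 1L else 2L
  rowSums(posterior[, risk_classes(trait, k), drop = FALSE])
}

# Observed counts / cohort size for one trait.
trait_data <- function(table, cohorts, trait) {
  if (trait == 1L) {
    list(y = table$y1, n = cohorts$n1)
  } else {
    if (is.null(table$y2)) stop("table has no y2 column; trait 2 unavailable")
    list(y = table$y2, n = cohorts$n2)
  }
}

#' Closed-form M-step for an intercept-only effect
#'
#' Without annotations the trait's effect is the scalar intercept and the
#' weighted Poisson M-step has the analytic solution
#' `beta = log( sum_i w_i Y_i / sum_i w_i 2 N mu_i )` with posterior risk
#' weights `w_i` (`Z_i10 + Z_i11` for trait 1, `Z_i01 + Z_i11` for trait 2).
#'
#' @param posterior Posterior matrix from [e_step()].
#' @param table,cohorts Gene table and cohort sizes.
#' @param trait 1 or 2.
#' @return The scalar intercept.
#' @export
m_step_beta_closed <- function(posterior, table, cohorts, trait = 1L) {
  w <- trait_weights(posterior, trait)
  td <- trait_data(table, cohorts, trait)
  num <- sum(td$y * w)
  den <- sum(2 * td$n * table$mu * w)
  if (den <= 0) stop("all posterior risk weight vanished for trait ", trait)
  if (num == 0) {
    stop("weighted count sum is zero for trait ", trait,
         ": the relative risk estimate degenerates to 0")
  }
  log(num / den)
}

# Gradient and (negative) Hessian of the Q-function in beta for one trait,
# plus the beta-dependent part of Q itself.
beta_q_parts <- function(beta, y, base, X, w, gene_id) {
  eta <- as.vector(X %*% beta)
  lam <- base * exp(eta)
  if (any(!is.finite(lam))) {
    stop("relative risk overflow (exp(x'beta) non-finite) at gene ",
         gene_id[which(!is.finite(lam))[1L]])
  }
  g <- crossprod(X, w * (y - lam))
  if (any(!is.finite(g))) {
    stop("non-finite gradient in Newton update (trait effect diverged)")
  }
  list(q = sum(w * (y * eta - lam)),
       grad = as.vector(g),
       neg_hess = crossprod(X * (w * lam), X))
}

#' One damped Newton-Raphson step for an annotation effect vector
#'
#' Performs a single safeguarded Newton update of `beta` for one trait,
#' maximizing the expected complete-data log-likelihood
#' `Q(beta) = sum_i w_i (Y_i x_i' beta - 2 N mu_i exp(x_i' beta))` with
#' posterior risk weights `w_i`. The step is halved (up to 30 times) until
#' `Q` does not decrease; a singular Hessian is regularized by a relative
#' ridge. At a zero gradient the input is returned unchanged.
#'
#' @param posterior Posterior matrix from [e_step()].
#' @param table,cohorts Gene table and cohort sizes.
#' @param design Design matrix for the trait (intercept column first).
#' @param beta_current Current effect vector.
#' @param trait 1 or 2.
#' @param ridge Relative ridge for a numerically singular Hessian.
#' @return The updated effect vector.
#' @export
newton_update_beta <- function(posterior, table, cohorts, design,
                               beta_current, trait = 1L, ridge = 1e-8) {
  w <- trait_weights(posterior, trait)
  td <- trait_data(table, cohorts, trait)
  base <- 2 * td$n * table$mu
  cur <- beta_q_parts(beta_current, td$y, base, design, w, table$gene_id)
  if (max(abs(cur$grad)) == 0) return(beta_current)
  H <- cur$neg_hess
  step <- tryCatch(solve(H, cur$grad), error = function(e) NULL)
  if (is.null(step) || any(!is.finite(step))) {
    H <- H + diag(ridge * sum(diag(H)) / ncol(H), ncol(H))
    step <- solve(H, cur$grad)
  }
  t <- 1
  for (k in 0:30) {
    cand <- beta_current + t * step
    qc <- tryCatch(
      beta_q_parts(cand, td$y, base, design, w, table$gene_id)$q,
      error = function(e) -Inf)
    if (is.finite(qc) && qc >= cur$q) return(as.vector(cand))
    t <- t / 2
  }
  beta_current
}

# Inner M-step loop: damped Newton to convergence, warm-started at `beta`.
maximize_beta <- function(posterior, table, cohorts, design, beta, trait, opts) {
  w <- trait_weights(posterior, trait)
  td <- trait_data(table, cohorts, trait)
  base <- 2 * td$n * table$mu
  for (it in seq_len(opts$newton_max_iter)) {
    g <- beta_q_parts(beta, td$y, base, design, w, table$gene_id)$grad
    if (max(abs(g)) < opts$newton_grad_tol) break
    beta_new <- newton_update_beta(posterior, table, cohorts, design,
                                   beta, trait, opts$ridge)
    if (identical(beta_new, beta)) break  # no improving step left
    beta <- beta_new
  }
  beta
}

# Shared EM engine for the single- and two-trait mixtures.
em_engine <- function(table, cohorts, designs, opts, n_traits) {
  table <- validate_gene_table(table)
  m <- nrow(table)
  for (k in seq_along(designs)) {
    if (nrow(designs[[k]]) != m) {
      stop("design for trait ", k, " has ", nrow(designs[[k]]),
           " rows; gene table has ", m)
    }
  }

  # Initialization: interior pi, moment-matched intercept with gamma > 1.
  pi0 <- opts$init_pi
  if (identical(pi0, "default")) {
    pi0 <- if (n_traits == 2L) c(0.90, 0.04, 0.04, 0.02) else c(0.9, 0.1)
  }
  betas <- vector("list", n_traits)
  for (k in seq_len(n_traits)) {
    b0 <- opts$init_beta_intercept
    if (identical(b0, "moment")) {
      td <- trait_data(table, cohorts, k)
      b0 <- log(max(1.5, sum(td$y) / sum(2 * td$n * table$mu)))
    }
    betas[[k]] <- c(b0, rep(0, ncol(designs[[k]]) - 1L))
  }
  params <- if (n_traits == 2L) {
    mixture_params(pi0, betas[[1L]], betas[[2L]])
  } else {
    mixture_params(pi0, betas[[1L]])
  }

  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(opts$max_em_iter)) {
    post <- e_step(table, cohorts, designs, params)
    ll <- attr(post, "loglik")
    trace <- c(trace, ll)
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (abs(ll - prev) < opts$loglik_rel_tol * (abs(prev) + 1e-3)) {
        converged <- TRUE
        break
      }
    }
    # M-step: pi with a floor against complete class collapse, then betas.
    pi_new <- m_step_pi(post)
    if (any(pi_new < 1e-12)) {
      pi_new <- pmax(pi_new, 1e-12)
      pi_new <- pi_new / sum(pi_new)
    }
    for (k in seq_len(n_traits)) {
      betas[[k]] <- if (is_intercept_only(designs[[k]])) {
        tryCatch(m_step_beta_closed(post, table, cohorts, k),
                 error = function(e) {
                   warning("trait ", k, " M-step at boundary (",
                           conditionMessage(e), "); keeping previous value",
                           call. = FALSE)
                   betas[[k]]
                 })
      } else {
        maximize_beta(post, table, cohorts, designs[[k]], betas[[k]], k, opts)
      }
    }
    params <- if (n_traits == 2L) {
      mixture_params(pi_new, betas[[1L]], betas[[2L]])
    } else {
      mixture_params(pi_new, betas[[1L]])
    }
  }
  if (!converged) {
    warning("EM did not converge in ", opts$max_em_iter, " iterations",
            call. = FALSE)
  }
  intercepts <- vapply(seq_len(n_traits), function(k) params[[paste0("beta", k)]][1L], 0)
  if (any(intercepts <= 0)) {
    warning("fitted relative-risk intercept <= 0 for trait ",
            paste(which(intercepts <= 0), collapse = ", "),
            " (estimated gamma <= 1, against the model's burden assumption)",
            call. = FALSE)
  }
  rownames(post) <- table$gene_id
  structure(list(params = params,
                 posterior = post,
                 loglik_trace = trace,
                 converged = converged,
                 n_iter = length(trace),
                 n_traits = n_traits,
                 gene_id = table$gene_id,
                 table = table,
                 cohorts = cohorts,
                 designs = designs,
                 options = opts),
            class = "dnm_fit")
}

#' Fit the two-trait mixture model by EM
#'
#' Alternates the E-step with the analytic `pi` update and per-trait effect
#' updates (closed form for intercept-only designs, damped Newton-Raphson
#' otherwise) until the marginal log-likelihood stabilizes. The
#' log-likelihood trace is non-decreasing; non-convergence yields a warning
#' and `converged = FALSE`, not an error.
#'
#' @param table Gene table with columns `gene_id`, `mu`, `y1`, `y2`.
#' @param cohorts Cohort sizes from [cohort_info()] (both `n1` and `n2`).
#' @param design1,design2 Per-trait design matrices from [make_design()];
#'   `NULL` means intercept-only (no annotations).
#' @param options A [fit_options()] list.
#' @return A `dnm_fit` object: `params`, `posterior`, `loglik_trace`,
#'   `converged`, `n_iter`.
#' @export
fit_multi <- function(table, cohorts, design1 = NULL, design2 = NULL,
                      options = fit_options()) {
  if (is.null(table$y2)) stop("fit_multi requires a y2 column (two cohorts)")
  if (is.null(cohorts$n2)) stop("fit_multi requires cohort size n2")
  m <- nrow(table)
  if (is.null(design1)) design1 <- make_design(m = m)
  if (is.null(design2)) design2 <- make_design(m = m)
  em_engine(table, cohorts, list(design1, design2), options, n_traits = 2L)
}

#' Fit the single-trait mixture model by EM
#'
#' The two-class (`Z = 0/1`) analogue of [fit_multi()]: identical EM
#' machinery on one cohort's counts.
#'
#' @param table Gene table with columns `gene_id`, `mu`, `y1` (any `y2` is
#'   ignored).
#' @param cohorts Cohort sizes; only `n1` is used.
#' @param design Design matrix, or `NULL` for intercept-only.
#' @param options A [fit_options()] list.
#' @return A `dnm_fit` object with length-2 `pi`.
#' @export
fit_single <- function(table, cohorts, design = NULL, options = fit_options()) {
  table <- table[setdiff(names(table), "y2")]
  if (is.null(design)) design <- make_design(m = nrow(table))
  em_engine(table, list(n1 = cohorts$n1), list(design), options, n_traits = 1L)
}

#' @export
print.dnm_fit <- function(x, ...) {
  cat("DNM mixture fit (", x$n_traits, " trait", if (x$n_traits > 1L) "s",
      ", ", length(x$gene_id), " genes)\n", sep = "")
  cat("  converged:", x$converged, "after", x$n_iter, "EM iterations\n")
  cat("  log-likelihood:",
      format(x$loglik_trace[length(x$loglik_trace)], digits = 10), "\n")
  print(x$params)
  invisible(x)
}
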