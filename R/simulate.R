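#' Class proportions from marginal risk proportions and overlap
#'
#' Builds the 4-class vector `(pi00, pi10, pi01, pi11)` from the per-trait
#' risk-gene proportions and the shared proportion `pi11`. Under
#' independence of the two traits' risk indicators,
#' `pi11 = margin1 * margin2`; the gap between `pi11` and that product
#' measures global pleiotropy.
#'
#' @param margin1,margin2 Marginal risk proportions `pi10 + pi11` and
#'   `pi01 + pi11`.
#' @param pi11 Shared risk proportion; must not exceed either margin.
#' @return Length-4 probability vector named `(00, 10, 01, 11)`.
#' @export
pi_from_margins <- function(margin1, margin2, pi11) {
  stopifnot(margin1 > 0, margin1 < 1, margin2 > 0, margin2 < 1,
            pi11 >= 0, pi11 <= margin1, pi11 <= margin2)
  pi <- c(1 - margin1 - margin2 + pi11, margin1 - pi11, margin2 - pi11, pi11)
  if (pi[1L] < 0) stop("margins and pi11 imply a negative pi00")
  stats::setNames(pi, c("00", "10", "01", "11"))
}

#' Sample per-gene mutabilities
#'
#' Draws `m` mutabilities from a truncated log-normal law:
#' `log10(mu) ~ Normal(mean, sd)` truncated to `[lo, hi]`, sampled by
#' inverse-CDF so the bounds are exact. The default law
#' (`mean = -5`, `sd = 0.7`, bounds `[-8, -3.5]`) emulates the scale of
#' exome-wide damaging-class mutabilities; a user-supplied mutability table
#' can be used instead anywhere a gene table is accepted.
#'
#' @param m Number of genes.
#' @param law List with entries `mean`, `sd`, `lo`, `hi` on the log10 scale.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return Numeric vector of `m` mutabilities in `[10^lo, 10^hi]`.
#' @export
sample_mutabilities <- function(m,
                                law = list(mean = -5, sd = 0.7,
                                           lo = -8, hi = -3.5),
                                seed = NULL) {
  if (!all(c("mean", "sd", "lo", "hi") %in% names(law)) ||
      !is.finite(law$sd) || law$sd <= 0 || law$lo >= law$hi) {
    stop("invalid mutability law: need mean, sd > 0, lo < hi (log10 scale)")
  }
  if (!is.null(seed)) set.seed(seed)
  p_lo <- stats::pnorm(law$lo, law$mean, law$sd)
  p_hi <- stats::pnorm(law$hi, law$mean, law$sd)
  u <- stats::runif(m, p_lo, p_hi)
  10^stats::qnorm(u, law$mean, law$sd)
}

#' Simulation settings
#'
#' Captures one generative setting of the simulation study. Under the
#' `"true"` model, latent classes are multinomial with proportions `pi`,
#' per-trait annotations are i.i.d. Bernoulli(`bernoulli_p`), relative risk
#' follows the exponential link `gamma = exp(x' beta)`, and counts are
#' Poisson with class-appropriate means `2 N mu gamma`. Under the
#' `"misspecified"` model, annotations act on the latent class through a
#' multinomial-logistic link and the relative risk is the constant
#' `gamma_fixed`. Only the annotations listed in `observed` are exposed to
#' the fitted model; the rest influence the data but stay hidden.
#'
#' @param m_genes Number of genes (default 10000).
#' @param n1,n2 Cohort sizes (trios).
#' @param pi Length-4 class-proportion vector, e.g. from
#'   [pi_from_margins()].
#' @param beta1,beta2 Per-trait effect vectors (intercept first); their
#'   length minus 1 sets the number of annotations per trait.
#' @param observed Integer indices of the annotations visible to the
#'   analyst (default: all).
#' @param bernoulli_p Success probability of the annotation indicators.
#' @param model `"true"` or `"misspecified"`.
#' @param gamma_fixed Fixed relative risk under the misspecified model
#'   (default 25; must exceed 1).
#' @param mutability Truncated log-normal law, as in
#'   [sample_mutabilities()].
#' @param n_replicates Replicates per setting (default 50).
#' @param base_seed Base RNG seed; replicate `r` uses `base_seed + r`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_genes = 10000L,
                       n1, n2 = n1,
                       pi = pi_from_margins(0.1, 0.1, 0.05),
                       beta1 = c(3, 0.1, 0.1),
                       beta2 = beta1,
                       observed = NULL,
                       bernoulli_p = 0.5,
                       model = c("true", "misspecified"),
                       gamma_fixed = 25,
                       mutability = list(mean = -5, sd = 0.7,
                                         lo = -8, hi = -3.5),
                       n_replicates = 50L,
                       base_seed = 20260L) {
  model <- match.arg(model)
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-10) {
    stop("pi must be a length-4 probability vector")
  }
  p_anno <- length(beta1) - 1L
  if (length(beta2) - 1L != p_anno) {
    stop("beta1 and beta2 must imply the same number of annotations")
  }
  if (is.null(observed)) observed <- seq_len(p_anno)
  if (length(observed) && (any(observed < 1L) || any(observed > p_anno))) {
    stop("observed annotation indices out of range 1..", p_anno)
  }
  if (model == "misspecified" && gamma_fixed <= 1) {
    stop("gamma_fixed must exceed 1 under the misspecified model")
  }
  stopifnot(bernoulli_p > 0, bernoulli_p < 1, m_genes >= 1, n1 >= 1, n2 >= 1,
            n_replicates >= 1)
  structure(list(m_genes = as.integer(m_genes),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 pi = stats::setNames(pi, c("00", "10", "01", "11")),
                 beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
                 n_annotations = p_anno,
                 observed = as.integer(observed),
                 bernoulli_p = bernoulli_p,
                 model = model,
                 gamma_fixed = gamma_fixed,
                 mutability = mutability,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "sim_config")
}

# Shared scaffolding for both generators: seed, mutabilities, annotations.
sim_scaffold <- function(config, rep_index) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$base_seed + as.integer(rep_index))
  m <- config$m_genes
  p <- config$n_annotations
  bern <- function() {
    x <- matrix(stats::rbinom(m * p, 1L, config$bernoulli_p), m, p)
    if (p > 0L) colnames(x) <- paste0("anno", seq_len(p))
    x
  }
  list(mu = sample_mutabilities(m, config$mutability),
       a1 = bern(), a2 = bern())
}

sim_assemble <- function(config, mu, a1, a2, z, gam1, gam2) {
  m <- config$m_genes
  risk1 <- z %in% c(2L, 4L)
  risk2 <- z %in% c(3L, 4L)
  lam1 <- 2 * config$n1 * mu * ifelse(risk1, gam1, 1)
  lam2 <- 2 * config$n2 * mu * ifelse(risk2, gam2, 1)
  table <- data.frame(gene_id = sprintf("g%05d", seq_len(m)),
                      mu = mu,
                      y1 = stats::rpois(m, lam1),
                      y2 = stats::rpois(m, lam2),
                      stringsAsFactors = FALSE)
  obs <- config$observed
  designs <- list(
    make_design(if (length(obs)) a1[, obs, drop = FALSE] else NULL, m = m),
    make_design(if (length(obs)) a2[, obs, drop = FALSE] else NULL, m = m))
  truth <- data.frame(gene_id = table$gene_id,
                      class = c("00", "10", "01", "11")[z],
                      risk1 = risk1, risk2 = risk2,
                      stringsAsFactors = FALSE)
  list(table = table, designs = designs, truth = truth)
}

#' Simulate one replicate under the generative (correctly specified) model
#'
#' Draws latent classes from `Multinomial(1, pi)`, Bernoulli annotations per
#' trait, relative risks `gamma = exp(x' beta)` using *all* annotations, and
#' Poisson counts with the class-appropriate means. The returned designs
#' expose only the `observed` annotation subset; the full truth (class and
#' per-trait risk flags) is returned separately.
#'
#' @param config A [sim_config()] with `model = "true"`.
#' @param rep_index Replicate number; the RNG seed is
#'   `base_seed + rep_index`.
#' @return List with `table` (gene table), `designs` (per-trait design
#'   matrices of observed annotations), `truth` (data frame with `gene_id`,
#'   `class`, `risk1`, `risk2`).
#' @export
simulate_true_model <- function(config, rep_index = 1L) {
  if (config$model != "true") stop("config$model must be 'true'")
  sc <- sim_scaffold(config, rep_index)
  m <- config$m_genes
  z <- sample.int(4L, m, replace = TRUE, prob = config$pi)
  gam1 <- exp(as.vector(cbind(1, sc$a1) %*% config$beta1))
  gam2 <- exp(as.vector(cbind(1, sc$a2) %*% config$beta2))
  sim_assemble(config, sc$mu, sc$a1, sc$a2, z, gam1, gam2)
}

#' Simulate one replicate under the misspecified model
#'
#' Robustness scenario: annotations act on the latent class, not on the
#' relative risk. Class probabilities follow the multinomial-logistic form
#' `P(Z_10) = e1 / (1 + e1 + e2 + e1 e2)` (and its analogues) with
#' `e_k = exp(x_k' beta_k)`, which factorizes into two independent logistic
#' Bernoulli draws, one per trait. Risk genes get the fixed relative risk
#' `gamma_fixed` (default 25).
#'
#' @param config A [sim_config()] with `model = "misspecified"`.
#' @param rep_index Replicate number.
#' @return Same structure as [simulate_true_model()].
#' @export
simulate_misspecified <- function(config, rep_index = 1L) {
  if (config$model != "misspecified") stop("config$model must be 'misspecified'")
  sc <- sim_scaffold(config, rep_index)
  m <- config$m_genes
  p1 <- stats::plogis(as.vector(cbind(1, sc$a1) %*% config$beta1))
  p2 <- stats::plogis(as.vector(cbind(1, sc$a2) %*% config$beta2))
  r1 <- stats::rbinom(m, 1L, p1)
  r2 <- stats::rbinom(m, 1L, p2)
  z <- 1L + r1 + 2L * r2  # (0,0)->00, (1,0)->10, (0,1)->01, (1,1)->11
  sim_assemble(config, sc$mu, sc$a1, sc$a2, z,
               config$gamma_fixed, config$gamma_fixed)
}

#' Score one replicate against the simulation truth
#'
#' Computes, for one trait, the power (fraction of true risk genes
#' rejected), the empirical false discovery proportion
#' (false rejections / max(1, rejections)), the type-I error rate
#' (false rejections / null genes), and the AUC of ranking genes by
#' `1 - Jlfdr` (probability a random risk gene out-ranks a random null
#' gene, ties counted one half).
#'
#' @param test Result table from [run_inference()].
#' @param truth Truth data frame from the simulators.
#' @param trait 1 or 2.
#' @return A one-row data frame `power`, `fdr`, `type1`, `auc`,
#'   `n_rejected`; power is `NA` when the replicate holds no risk genes.
#' @export
evaluate_replicate <- function(test, truth, trait = 1L) {
  stopifnot(trait %in% c(1L, 2L))
  i <- match(test$gene_id, truth$gene_id)
  if (any(is.na(i))) stop("truth labels do not cover all tested genes")
  risk <- truth[[paste0("risk", trait)]][i]
  sig_col <- paste0("sig_t", trait)
  j_col <- paste0("jlfdr_t", trait)
  if (!sig_col %in% names(test)) stop("test table has no trait-", trait, " results")
  rej <- test[[sig_col]]
  n_risk <- sum(risk)
  n_null <- sum(!risk)
  fp <- sum(rej & !risk)
  score <- 1 - test[[j_col]]
  auc <- if (n_risk == 0L || n_null == 0L) NA_real_ else {
    r <- rank(score, ties.method = "average")
    (sum(r[risk]) - n_risk * (n_risk + 1) / 2) / (n_risk * n_null)
  }
  data.frame(power = if (n_risk == 0L) NA_real_ else sum(rej & risk) / n_risk,
             fdr = fp / max(1L, sum(rej)),
             type1 = if (n_null == 0L) NA_real_ else fp / n_null,
             auc = auc,
             n_rejected = sum(rej))
}

# Fit one method on one simulated replicate and score the requested trait(s).
fit_and_score <- function(sim, method, cohorts, q, options) {
  multi <- startsWith(method, "multi")
  anno <- endsWith(method, "_anno")
  m <- nrow(sim$table)
  if (multi) {
    d1 <- if (anno) sim$designs[[1L]] else NULL
    d2 <- if (anno) sim$designs[[2L]] else NULL
    fit <- fit_multi(sim$table, cohorts, d1, d2, options)
    test <- run_inference(fit, q)
    rows <- lapply(1:2, function(tr) {
      cbind(trait = tr, evaluate_replicate(test, sim$truth, tr))
    })
    est <- data.frame(pi11_hat = fit$params$pi[["11"]],
                      pi1_hat = fit$params$pi[["10"]] + fit$params$pi[["11"]],
                      pi2_hat = fit$params$pi[["01"]] + fit$params$pi[["11"]])
  } else {
    rows <- vector("list", 2L)
    pis <- numeric(2L)
    for (tr in 1:2) {
      tab <- sim$table
      if (tr == 2L) tab$y1 <- tab$y2
      tab$y2 <- NULL
      co <- list(n1 = if (tr == 1L) cohorts$n1 else cohorts$n2)
      d <- if (anno) sim$designs[[tr]] else NULL
      fit <- fit_single(tab, co, d, options)
      test <- run_inference(fit, q)
      names(test)[names(test) %in% c("jlfdr_t1", "fdr_t1", "sig_t1")] <-
        paste0(c("jlfdr_t", "fdr_t", "sig_t"), tr)
      rows[[tr]] <- cbind(trait = tr, evaluate_replicate(test, sim$truth, tr))
      pis[tr] <- fit$params$pi[["1"]]
    }
    est <- data.frame(pi11_hat = NA_real_, pi1_hat = pis[1L], pi2_hat = pis[2L])
  }
  cbind(do.call(rbind, rows), est)
}

#' Run a replicate grid of simulation settings
#'
#' For every setting, replicate, and method: simulate, fit, test at level
#' `q`, and score both traits. Replicate `r` of every setting uses seed
#' `base_seed + r`, so grids are deterministic and parallelize by
#' replicate. A failed replicate is recorded with `NA` metrics and a
#' warning, not an error.
#'
#' @param configs A single [sim_config()] or a named list of them (names
#'   become the `setting` column).
#' @param methods Subset of `"multi_anno"`, `"multi_noanno"`,
#'   `"single_anno"`, `"single_noanno"`.
#' @param q Nominal global Fdr level.
#' @param options [fit_options()] for every fit.
#' @param n_replicates Override of each config's replicate count.
#' @return Long-format data frame: `setting`, `replicate`, `method`,
#'   `trait`, `power`, `fdr`, `type1`, `auc`, `n_rejected`, `pi11_hat`,
#'   `pi1_hat`, `pi2_hat`.
#' @export
run_grid <- function(configs,
                     methods = c("multi_anno", "multi_noanno",
                                 "single_anno", "single_noanno"),
                     q = 0.05, options = fit_options(),
                     n_replicates = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(setting1 = configs)
  if (is.null(names(configs))) {
    names(configs) <- paste0("setting", seq_along(configs))
  }
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (nm in names(configs)) {
    config <- configs[[nm]]
    n_rep <- if (is.null(n_replicates)) config$n_replicates else n_replicates
    cohorts <- cohort_info(config$n1, config$n2)
    for (r in seq_len(n_rep)) {
      sim <- if (config$model == "true") {
        simulate_true_model(config, r)
      } else {
        simulate_misspecified(config, r)
      }
      for (method in methods) {
        res <- tryCatch(
          fit_and_score(sim, method, cohorts, q, options),
          error = function(e) {
            warning("setting ", nm, ", replicate ", r, ", method ", method,
                    " failed: ", conditionMessage(e), call. = FALSE)
            data.frame(trait = 1:2, power = NA_real_, fdr = NA_real_,
                       type1 = NA_real_, auc = NA_real_,
                       n_rejected = NA_integer_, pi11_hat = NA_real_,
                       pi1_hat = NA_real_, pi2_hat = NA_real_)
          })
        out[[length(out) + 1L]] <- cbind(
          data.frame(setting = nm, replicate = r, method = method,
                     stringsAsFactors = FALSE),
          res)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a replicate grid
#'
#' Means and Monte-Carlo standard errors (sd / sqrt(replicates)) of every
#' metric by setting, method, and trait.
#'
#' @param metrics Output of [run_grid()].
#' @return Data frame with `mean_*` and `se_*` columns per metric.
#' @export
summarize_grid <- function(metrics) {
  key_cols <- c("setting", "method", "trait")
  val_cols <- setdiff(names(metrics), c(key_cols, "replicate"))
  keys <- unique(metrics[key_cols])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- metrics$setting == keys$setting[i] &
      metrics$method == keys$method[i] & metrics$trait == keys$trait[i]
    sub <- metrics[sel, val_cols, drop = FALSE]
    stats_row <- keys[i, , drop = FALSE]
    for (v in val_cols) {
      x <- sub[[v]][!is.na(sub[[v]])]
      stats_row[[paste0("mean_", v)]] <- if (length(x)) mean(x) else NA_real_
      stats_row[[paste0("se_", v)]] <- if (length(x) > 1L) {
        stats::sd(x) / sqrt(length(x))
      } else {
        NA_real_
      }
    }
    stats_row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
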