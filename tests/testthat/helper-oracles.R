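# Independent brute-force oracles, kept deliberately naive: probability-space
# Poisson pmfs and direct Bayes arithmetic, no reuse of package internals.

# Poisson pmf from first principles (safe for the small means used in tests).
naive_pois <- function(y, lam) lam^y * exp(-lam) / factorial(y)

# Probability of (y1, y2) under one latent class, probability space.
naive_class_lik <- function(y1, y2, n1, n2, mu, g1, g2, label) {
  r1 <- if (substr(label, 1, 1) == "1") g1 else 1
  out <- naive_pois(y1, 2 * n1 * mu * r1)
  if (!is.null(y2)) {
    r2 <- if (substr(label, 2, 2) == "1") g2 else 1
    out <- out * naive_pois(y2, 2 * n2 * mu * r2)
  }
  out
}

# Direct Bayes posterior over the four classes for a single gene.
naive_posterior <- function(y1, y2, n1, n2, mu, g1, g2, pi) {
  labels <- c("00", "10", "01", "11")
  num <- vapply(seq_along(labels), function(l) {
    pi[l] * naive_class_lik(y1, y2, n1, n2, mu, g1, g2, labels[l])
  }, 0)
  num / sum(num)
}

# Tiny deterministic two-trait dataset for fitting tests.
toy_table <- function(m = 30, seed = 7, two_traits = TRUE) {
  set.seed(seed)
  mu <- 10^runif(m, -6, -4.5)
  risk <- seq_len(m) <= ceiling(m / 5)
  y1 <- rpois(m, 2 * 1000 * mu * ifelse(risk, 20, 1))
  tab <- data.frame(gene_id = sprintf("G%03d", seq_len(m)), mu = mu, y1 = y1,
                    stringsAsFactors = FALSE)
  if (two_traits) tab$y2 <- rpois(m, 2 * 1500 * mu * ifelse(risk, 15, 1))
  tab
}

# Direct numeric maximization of the marginal log-likelihood over (pi, beta)
# via unconstrained reparameterization (logit/softmax for pi). Serves as the
# independent optimizer oracle for EM solutions.
optim_loglik <- function(table, cohorts, designs, n_traits, n_starts = 3,
                         seed = 1) {
  p_len <- if (n_traits == 2) 4 else 2
  b_lens <- vapply(designs, ncol, 0L)
  unpack <- function(theta) {
    a <- c(0, theta[seq_len(p_len - 1)])
    pi <- exp(a - max(a)); pi <- pi / sum(pi)
    off <- p_len - 1
    beta1 <- theta[off + seq_len(b_lens[1])]
    beta2 <- if (n_traits == 2) theta[off + b_lens[1] + seq_len(b_lens[2])] else NULL
    mixture_params(pi, beta1, beta2)
  }
  nll <- function(theta) {
    -marginal_loglik(table, cohorts, designs, unpack(theta))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    init <- c(rnorm(p_len - 1, -2, 0.5),
              unlist(lapply(b_lens, function(k) c(runif(1, 0.5, 3),
                                                  rep(0, k - 1)))))
    fit <- optim(init, nll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  -best
}
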