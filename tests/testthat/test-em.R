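test_that("E-step posterior equals direct Bayes arithmetic", {
  # single gene with 2*N1*mu = 2*N2*mu = 0.1 and gamma1 = gamma2 = 20
  tab <- data.frame(gene_id = "g1", mu = 1e-5, y1 = 2, y2 = 0)
  co <- cohort_info(5000, 5000)
  designs <- list(make_design(m = 1), make_design(m = 1))
  pi <- c(0.9, 0.04, 0.04, 0.02)
  params <- mixture_params(pi, log(20), log(20))
  post <- e_step(tab, co, designs, params)
  want <- naive_posterior(2, 0, 5000, 5000, 1e-5, 20, 20, pi)
  expect_equal(as.vector(post), want, tolerance = 1e-12)

  # a batch of genes against the same oracle
  tab2 <- toy_table(m = 20, seed = 3)
  co2 <- cohort_info(1000, 1500)
  d2 <- list(make_design(m = 20), make_design(m = 20))
  params2 <- mixture_params(c(0.85, 0.06, 0.05, 0.04), log(18), log(9))
  post2 <- e_step(tab2, co2, d2, params2)
  for (i in c(1, 7, 20)) {
    expect_equal(as.vector(post2[i, ]),
                 naive_posterior(tab2$y1[i], tab2$y2[i], 1000, 1500,
                                 tab2$mu[i], 18, 9,
                                 c(0.85, 0.06, 0.05, 0.04)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(post2)), rep(1, 20), tolerance = 1e-8)
})

test_that("E-step degenerates correctly for flat likelihoods and point priors", {
  tab <- toy_table(m = 8)
  co <- cohort_info(1000, 1500)
  designs <- list(make_design(m = 8), make_design(m = 8))
  # gamma = 1 in both traits: all class likelihoods equal, posterior = pi
  pi <- c(0.7, 0.1, 0.15, 0.05)
  flat <- e_step(tab, co, designs, mixture_params(pi, 0, 0))
  for (i in seq_len(8)) {
    expect_equal(as.vector(flat[i, ]), pi, tolerance = 1e-12)
  }
  # degenerate prior pins the posterior
  point <- e_step(tab, co, designs, mixture_params(c(1, 0, 0, 0), 3, 3))
  expect_equal(unname(point[, "00"]), rep(1, 8))
})

test_that("M-step for pi is the posterior column mean", {
  post <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(unname(m_step_pi(post)), c(0.5, 0.5, 0, 0))
  v <- c(0.6, 0.2, 0.15, 0.05)
  expect_equal(unname(m_step_pi(rbind(v, v, v))), v)
  set.seed(5)
  r <- matrix(rexp(40), 10, 4)
  r <- r / rowSums(r)
  expect_equal(unname(m_step_pi(r)), colSums(r) / 10, tolerance = 1e-14)
  expect_error(m_step_pi(matrix(numeric(0), 0, 4)), "empty")
})

test_that("closed-form intercept M-step matches formula and 1-D maximization", {
  # weights all 1, sum(Y) = 40, sum(2*N*mu) = 2  ->  log 20
  tab <- data.frame(gene_id = paste0("g", 1:4), mu = rep(2.5e-5, 4),
                    y1 = c(10, 10, 10, 10), y2 = 0)
  co <- cohort_info(10000, 10000)
  post <- matrix(c(0, 0.5, 0, 0.5), 4, 4, byrow = TRUE,
                 dimnames = list(NULL, c("00", "10", "01", "11")))
  expect_equal(m_step_beta_closed(post, tab, co, 1), log(20))

  # sum(Y w) = sum(2 N mu w)  ->  gamma-hat = 1, beta = 0
  tab0 <- data.frame(gene_id = "g1", mu = 1e-4, y1 = 2, y2 = 0)
  co0 <- cohort_info(10000, 10000)
  expect_equal(m_step_beta_closed(post[1, , drop = FALSE], tab0, co0, 1), 0)

  # randomized instance: equals the argmax of Q over beta found by grid search
  set.seed(9)
  cor_ <- cohort_info(1000, 1500)
  tabr <- data.frame(gene_id = sprintf("r%02d", 1:12),
                     mu = 10^runif(12, -4.2, -3.8),
                     y1 = rpois(12, 2), y2 = 0)
  stopifnot(sum(tabr$y1) > 0)
  pr <- matrix(rexp(48), 12, 4)
  pr <- pr / rowSums(pr)
  colnames(pr) <- c("00", "10", "01", "11")
  bhat <- m_step_beta_closed(pr, tabr, cor_, 1)
  w <- pr[, "10"] + pr[, "11"]
  qfun <- function(b) sum(w * (tabr$y1 * b - 2 * 1000 * tabr$mu * exp(b)))
  grid <- seq(bhat - 2, bhat + 2, length.out = 40001)
  expect_equal(bhat, grid[which.max(vapply(grid, qfun, 0))], tolerance = 1e-4)

  # degenerate weighted count sum is a boundary error
  tabz <- data.frame(gene_id = "g1", mu = 1e-5, y1 = 0, y2 = 0)
  expect_error(m_step_beta_closed(post[1, , drop = FALSE], tabz, co, 1),
               "degenerates")
})

test_that("damped Newton agrees with the closed form and an optimizer oracle", {
  # counts generated at a well-identified interior optimum: every annotation
  # cell carries positive weighted counts, so the maximizer is finite
  set.seed(13)
  co <- cohort_info(1000, 1500)
  a <- rep(0:1, length.out = 25)
  b_cov <- runif(25, -1, 1)
  mu <- 10^runif(25, -3.9, -3.6)
  tab <- data.frame(gene_id = sprintf("n%02d", 1:25), mu = mu,
                    y1 = rpois(25, 2 * 1000 * mu * exp(1 + 0.5 * a + 0.3 * b_cov)),
                    y2 = 0)
  pr <- matrix(rexp(100, rate = c(1, 2, 4, 2)), 25, 4, byrow = TRUE)
  pr <- pr / rowSums(pr)
  colnames(pr) <- c("00", "10", "01", "11")
  stopifnot(sum(tab$y1[a == 0]) > 0, sum(tab$y1[a == 1]) > 0)

  # intercept-only: Newton iterated to convergence reproduces the closed form
  d0 <- make_design(m = 25)
  b <- 0.5
  for (k in 1:50) b <- newton_update_beta(pr, tab, co, d0, b, trait = 1)
  expect_equal(b, m_step_beta_closed(pr, tab, co, 1), tolerance = 1e-8)

  # zero gradient: the update is a fixed point
  bstar <- m_step_beta_closed(pr, tab, co, 1)
  w <- pr[, "10"] + pr[, "11"]
  expect_equal(newton_update_beta(pr, tab, co, d0, bstar, 1), bstar,
               tolerance = 1e-10)

  # two features: converged Newton matches direct numeric maximization of Q
  X <- make_design(cbind(a = a, b = b_cov))
  bn <- c(1, 0, 0)
  for (k in 1:100) bn <- newton_update_beta(pr, tab, co, X, bn, trait = 1)
  negq <- function(beta) {
    eta <- as.vector(X %*% beta)
    -sum(w * (tab$y1 * eta - 2 * 1000 * tab$mu * exp(eta)))
  }
  opt <- optim(c(1, 0, 0), negq, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(bn, opt$par, tolerance = 1e-5)
})

test_that("EM log-likelihood trace is monotone and rows stay normalized", {
  tab <- toy_table(m = 40, seed = 21)
  co <- cohort_info(1000, 1500)
  set.seed(21)
  d1 <- make_design(matrix(rbinom(40, 1, .5), ncol = 1,
                           dimnames = list(NULL, "a1")))
  d2 <- make_design(matrix(rbinom(40, 1, .5), ncol = 1,
                           dimnames = list(NULL, "a1")))
  fit <- fit_multi(tab, co, d1, d2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 40), tolerance = 1e-8)
  expect_equal(unname(sum(fit$params$pi)), 1, tolerance = 1e-10)
  expect_lte(fit$n_iter, fit$options$max_em_iter)

  sfit <- fit_single(tab, co)
  expect_true(all(diff(sfit$loglik_trace) >= -1e-8))
  expect_length(sfit$params$pi, 2)
})

test_that("no-annotation fit equals the annotation fit with intercept-only design", {
  tab <- toy_table(m = 60, seed = 31)
  co <- cohort_info(1000, 1500)
  m <- nrow(tab)
  fit_a <- fit_multi(tab, co, NULL, NULL)
  fit_b <- fit_multi(tab, co, make_design(m = m), make_design(m = m))
  expect_equal(fit_a$params$pi, fit_b$params$pi, tolerance = 1e-6)
  expect_equal(fit_a$params$beta1, fit_b$params$beta1, tolerance = 1e-6)
  expect_equal(fit_a$params$beta2, fit_b$params$beta2, tolerance = 1e-6)
})

test_that("EM matches direct numeric maximization on small instances", {
  co <- cohort_info(1000, 1500)
  for (seed in c(2, 17)) {
    tab <- toy_table(m = 40, seed = seed)
    designs <- list(make_design(m = 40), make_design(m = 40))
    fit <- fit_multi(tab, co)
    ll_em <- fit$loglik_trace[fit$n_iter]
    ll_opt <- optim_loglik(tab, co, designs, n_traits = 2, seed = seed)
    expect_gte(ll_em, ll_opt - 1e-4)
  }
})

test_that("pure-null data is flagged as degenerate and yields no discoveries", {
  # with no risk genes the mixture is unidentifiable: gamma collapses to ~1,
  # the class likelihoods merge, and pi wanders on a flat ridge -- the fit
  # must flag this (gamma <= 1 warning) rather than fail, and inference on
  # it must reject nothing
  cfg <- sim_config(m_genes = 10000, n1 = 2000, n2 = 2000,
                    pi = c(1, 0, 0, 0), beta1 = c(3), beta2 = c(3),
                    observed = integer(0), base_seed = 400)
  sim <- simulate_true_model(cfg, 1)
  expect_warning(fit <- fit_multi(sim$table, cohort_info(2000, 2000)),
                 "gamma <= 1")
  expect_lte(exp(fit$params$beta1[1]), 1.05)
  test <- run_inference(fit, q = 0.05)
  expect_equal(sum(test$sig_t1), 0)
  expect_equal(sum(test$sig_t2), 0)

  # zero-effect data drives the single-trait fit toward the boundary:
  # flagged by warnings, not fatal
  expect_warning(fit_single(sim$table, cohort_info(2000)),
                 "gamma|boundary|converge")
})

test_that("single-trait fit agrees with the multi-trait marginal under independence", {
  # truth with pi11 = margin1 * margin2: the traits are independent, so the
  # trait-1 marginal of the joint fit matches a single-trait fit
  cfg <- sim_config(m_genes = 10000, n1 = 5000, n2 = 5000,
                    pi = pi_from_margins(0.1, 0.1, 0.01),
                    beta1 = c(3), beta2 = c(3), observed = integer(0),
                    base_seed = 500)
  sim <- simulate_true_model(cfg, 1)
  fm <- fit_multi(sim$table, cohort_info(5000, 5000))
  fs <- fit_single(sim$table, cohort_info(5000))
  pi1_joint <- fm$params$pi[["10"]] + fm$params$pi[["11"]]
  expect_equal(fs$params$pi[["1"]], pi1_joint, tolerance = 0.02)
  expect_equal(fs$params$pi[["1"]], 0.1, tolerance = 0.02)
})
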