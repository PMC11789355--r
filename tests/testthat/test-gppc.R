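test_that("shrinkage Bayes factor reproduces its closed forms", {
  # direct arithmetic over the stated grid at W = 0, df = 2
  grid <- c(1, 2, 4, 8, 16)
  expect_equal(wald_to_log_bf(0, 2, grid),
               log(mean(1 / (1 + grid))))
  expect_equal(wald_to_log_bf(0, 1, tau_grid = 1), log(1 / sqrt(2)))
  expect_gt(wald_to_log_bf(10, 2, grid), wald_to_log_bf(5, 2, grid))
  expect_gt(wald_to_log_bf(10, 1, grid), wald_to_log_bf(5, 1, grid))
  expect_error(wald_to_log_bf(-1, 1), class = "multipcg_argument_error")
  expect_error(wald_to_log_bf(1, 3), class = "multipcg_argument_error")
  expect_error(wald_to_log_bf(1, 1, numeric(0)),
               class = "multipcg_argument_error")
})

test_that("bivariate model Bayes factors reduce and separate correctly", {
  grid <- c(1, 2, 4, 8, 16)
  # at rho = 0 and leak = 0 the single-product BFs equal the scalar form
  b <- model_log_bfs(3, 1.2, rho = 0, tau_grid = grid, leak = 0)
  expect_equal(b$log_bf_E, wald_to_log_bf(9, 1, grid), tolerance = 1e-10)
  expect_equal(b$log_bf_P, wald_to_log_bf(1.2^2, 1, grid), tolerance = 1e-10)

  # swapping the two scores swaps the single-product BFs exactly
  b1 <- model_log_bfs(4, 1, rho = 0.3)
  b2 <- model_log_bfs(1, 4, rho = 0.3)
  expect_equal(b1$log_bf_E, b2$log_bf_P)
  expect_equal(b1$log_bf_P, b2$log_bf_E)
  expect_equal(b1$log_bf_EP, b2$log_bf_EP)

  # a single-product signal whose leakage matches rho favors that model;
  # a genuine two-product signal favors the joint model
  rho <- 0.6
  one <- model_log_bfs(rho * 6, 6, rho = rho)
  expect_gt(one$log_bf_P, one$log_bf_EP)
  expect_gt(one$log_bf_P, one$log_bf_E)
  both <- model_log_bfs(6, 6, rho = 0.2)
  expect_gt(both$log_bf_EP, both$log_bf_E)

  expect_error(model_log_bfs(1, 1, 0, leak = -1),
               class = "multipcg_argument_error")
})

test_that("colocalization prior implements the truncated necessary condition", {
  expect_equal(prior_value(0.6, 0.1, pi = 0.5), 0.30)
  expect_equal(prior_value(0.01, 0.01, pi = 0.5), 0)
  # zero colocalization on both products is always prior zero
  for (shape in c("linear", "step")) {
    expect_equal(prior_f(0, 0, shape = shape, threshold = 0), 0)
  }
  expect_equal(prior_f(0.6, 0.2, shape = "step"), 1)
  expect_equal(prior_f(0.04, 0.03, shape = "step"), 0)
  expect_equal(prior_f(0.3, 0.2, combine = "one_minus_prod"),
               1 - 0.7 * 0.8)
  expect_error(prior_f(1.2, 0), class = "multipcg_argument_error")
})

test_that("pi estimation recovers mixtures and handles degenerate input", {
  set.seed(13)
  lbf <- c(rep(20, 500), rep(-20, 500))
  fit <- estimate_pi(lbf, rep(1, 1000))
  expect_equal(fit$pi, 0.5, tolerance = 0.05)
  expect_true(fit$converged)

  # null-dominated limit
  expect_lt(estimate_pi(rep(-50, 100), rep(1, 100))$pi, 1e-6)

  # flat likelihood returns the initialization with a warning
  expect_warning(flat <- estimate_pi(rep(0, 50), runif(50)), "flat")
  expect_equal(flat$pi, 0.5)

  # unidentifiable when every prior factor is zero
  expect_warning(zero <- estimate_pi(rnorm(50), rep(0, 50)),
                 "unidentifiable")
  expect_equal(zero$pi, 0)

  expect_error(estimate_pi(1, 1), class = "multipcg_argument_error")
})

test_that("gene probability of putative causality follows Bayes' rule", {
  expect_equal(compute_gppc(0.5, 0), 0.5)
  expect_equal(compute_gppc(0.1, log(9)), 0.5)
  expect_equal(compute_gppc(0, 100), 0)
  expect_equal(compute_gppc(1, -100), 1)
  expect_equal(compute_gppc(0.2, 1e4), 1, tolerance = 1e-12)
  # monotone in both arguments
  priors <- seq(0.05, 0.95, 0.1)
  expect_true(all(diff(compute_gppc(priors, 0.7)) > 0))
  lbfs <- seq(-5, 5, 0.5)
  expect_true(all(diff(compute_gppc(0.3, lbfs)) > 0))
})

test_that("Bayesian FDR control rejects by running-mean lfdr with tie blocks", {
  expect_equal(bayesian_fdr_control(c(0.01, 0.04, 0.20), 0.05),
               c(TRUE, TRUE, FALSE))
  expect_true(all(bayesian_fdr_control(rep(0, 5), 0.05)))
  # inclusive boundary
  expect_equal(bayesian_fdr_control(c(0.04, 0.06), 0.05), c(TRUE, TRUE))
  # ties at the boundary are all-or-none
  expect_equal(bayesian_fdr_control(c(0.01, 0.08, 0.08, 0.08), 0.05),
               c(TRUE, FALSE, FALSE, FALSE))
  # flags come back in the original order
  lf <- c(0.5, 0.01, 0.9, 0.02)
  expect_equal(bayesian_fdr_control(lf, 0.05), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(bayesian_fdr_control(numeric(0), 0.05), logical(0))
  expect_error(bayesian_fdr_control(c(0.2, 1.4), 0.05),
               class = "multipcg_argument_error")
  expect_error(bayesian_fdr_control(0.2, 0), class = "multipcg_argument_error")
})

test_that("per-gene Bayes factor table carries a bounded overall mixture", {
  set.seed(17)
  tbl <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                        z_E = rnorm(30, 0, 2), z_P = rnorm(30, 0, 2),
                        rho = runif(30, -0.5, 0.5),
                        W_E = rchisq(30, 1), W_P = rchisq(30, 1),
                        W_joint = rchisq(30, 2),
                        df_joint = rep(2L, 30))
  for (method in c("bivariate", "wald")) {
    bf <- gene_bayes_factors(tbl, method = method)
    lo <- pmin(bf$log_bf_E, bf$log_bf_P, bf$log_bf_EP)
    hi <- pmax(bf$log_bf_E, bf$log_bf_P, bf$log_bf_EP)
    expect_true(all(bf$log_bf_overall >= lo - 1e-9))
    expect_true(all(bf$log_bf_overall <= hi + 1e-9))
    expect_true(all(is.finite(bf$log_bf_overall)))
  }
  # degenerate mixture weight puts the overall BF on one model
  bf1 <- gene_bayes_factors(tbl, mixture = c(1, 0, 0))
  expect_equal(bf1$log_bf_overall, bf1$log_bf_E)
})
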