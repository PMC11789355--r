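test_that("model space enumeration covers p <= 4 and refuses larger p", {
  expect_equal(product_models(c("E", "P")),
               list("E", "P", c("E", "P")))
  expect_length(product_models(letters[1:4]), 15)
  expect_error(product_models(letters[1:5]), "at most 4",
               class = "multipcg_argument_error")
})

test_that("h estimation recovers single-component and symmetric mixtures", {
  set.seed(23)
  n <- 200
  # all genes generated under the expression-only model
  lbf <- cbind(E = rnorm(n, 10, 1), P = rnorm(n, -3, 1),
               EP = rnorm(n, 6, 1))
  fit <- em_estimate_h(lbf, rep(0.8, n))
  expect_gte(fit$h[["E"]], 0.95)
  expect_true(fit$converged)

  # swapping the E and P Bayes factor columns swaps h_E and h_P exactly
  tbl <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                        log_bf_E = lbf[, 1], log_bf_P = lbf[, 2],
                        log_bf_EP = lbf[, 3])
  swapped <- dplyr::rename(tbl, log_bf_E = log_bf_P, log_bf_P = log_bf_E)
  f1 <- em_estimate_h(tbl, rep(0.8, n))
  f2 <- em_estimate_h(swapped, rep(0.8, n))
  expect_equal(f1$h[["E"]], f2$h[["P"]])
  expect_equal(f1$h[["P"]], f2$h[["E"]])

  # row order does not matter (fixed gene_id accumulation order)
  shuf <- tbl[sample.int(n), ]
  f3 <- em_estimate_h(shuf, rep(0.8, n))
  expect_equal(f1$h, f3$h)

  expect_error(em_estimate_h(lbf, rep(0, n)),
               class = "multipcg_estimation_error")
})

test_that("h estimation agrees with simplex grid search and is monotone", {
  syn <- synthetic_bf_table(n = 400, seed = 29)
  pf <- rep(0.5, nrow(syn$lbf))
  fit <- em_estimate_h(syn$lbf, pf)
  # EM objective is non-decreasing every iteration
  expect_true(all(diff(fit$log_lik) >= -1e-8))
  # independent oracle: brute-force grid over the simplex (step 0.01)
  oracle <- h_grid_search(syn$lbf, pf)
  expect_equal(unname(fit$h), oracle, tolerance = 0.02)
})

test_that("mechanism proportions are recovered from mixture-generated tables", {
  # twenty replicates generated at (0.5, 0.25, 0.25); average within 0.1
  hs <- sapply(1:20, function(k) {
    syn <- synthetic_bf_table(n = 1198, h = c(0.5, 0.25, 0.25),
                              signal = 5, seed = 100 + k)
    em_estimate_h(syn$lbf, rep(0.5, nrow(syn$lbf)))$h
  })
  expect_equal(unname(rowMeans(hs)), c(0.5, 0.25, 0.25), tolerance = 0.1)
})

test_that("posterior model probabilities follow the stated arithmetic", {
  # no prior mass -> all on the null model
  p0 <- posterior_model_probs(5, 5, 5, prior_value = 0, h = rep(1 / 3, 3))
  expect_equal(p0$post_M0, 1)
  expect_equal(p0$post_MEP, 0)

  # flat Bayes factors, prior one half, uniform h
  p1 <- posterior_model_probs(0, 0, 0, prior_value = 0.5, h = rep(1 / 3, 3))
  expect_equal(unlist(p1), c(post_M0 = 0.5, post_ME = 1 / 6,
                             post_MP = 1 / 6, post_MEP = 1 / 6))

  # overwhelming joint evidence
  p2 <- posterior_model_probs(0, 0, 200, prior_value = 0.5,
                              h = rep(1 / 3, 3))
  expect_equal(p2$post_MEP, 1, tolerance = 1e-10)

  # rows always normalize
  set.seed(31)
  pr <- posterior_model_probs(rnorm(50), rnorm(50), rnorm(50),
                              prior_value = runif(50), h = c(0.5, 0.3, 0.2))
  expect_equal(rowSums(as.matrix(pr)), rep(1, 50), tolerance = 1e-8)
})

test_that("relevance probabilities marginalize the model posteriors", {
  mp <- tibble::tibble(post_M0 = 0.5, post_ME = 0.2, post_MP = 0,
                       post_MEP = 0.3)
  out <- relevance_probs(mp)
  expect_equal(out$relevance_E, 0.5)
  expect_equal(out$relevance_P, 0.3)
  expect_equal(relevance_probs(tibble::tibble(post_M0 = 1, post_ME = 0,
                                              post_MP = 0,
                                              post_MEP = 0))$relevance_E, 0)
  both <- relevance_probs(tibble::tibble(post_M0 = 0, post_ME = 0,
                                         post_MP = 0, post_MEP = 1))
  expect_equal(both$relevance_E, 1)
  expect_equal(both$relevance_P, 1)
})

test_that("fitted gene results keep relevance below the gene probability", {
  set.seed(37)
  n <- 120
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    log_bf_E = rnorm(n, 2, 3), log_bf_P = rnorm(n, 2, 3),
    log_bf_EP = rnorm(n, 2, 3),
    coloc_E = runif(n), coloc_P = runif(n))
  fit <- suppressWarnings(pcg_fit(genes))
  g <- fit$genes
  expect_equal(g$gppc + g$lfdr, rep(1, n))
  expect_equal(g$post_M0 + g$post_ME + g$post_MP + g$post_MEP,
               rep(1, n), tolerance = 1e-8)
  expect_equal(g$relevance_E, pmin(g$post_ME + g$post_MEP, 1))
  expect_true(all(pmax(g$relevance_E, g$relevance_P) <= g$gppc + 1e-8))
  # gppc is one minus the null posterior under the estimated-h mixture
  expect_equal(g$gppc, 1 - g$post_M0, tolerance = 1e-8)
})
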