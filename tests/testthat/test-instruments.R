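test_that("weight construction follows the stated selection rules", {
  assoc <- tibble::tibble(snp_id = c("snp1", "snp2"),
                          effect = c(0.5, -0.2), se = c(0.1, 0.1))
  w <- build_weights(assoc, method = "top_snp")
  expect_equal(w$snp_id, "snp1")
  expect_equal(w$weight, 0.5)

  wp <- build_weights(assoc, method = "pip_weighted", pip = c(1, 0))
  expect_equal(wp$weight, c(0.5, 0))

  # exact |z| tie -> lexicographically smaller snp_id
  tie <- tibble::tibble(snp_id = c("snpB", "snpA"),
                        effect = c(0.4, -0.4), se = c(0.1, 0.1))
  expect_equal(build_weights(tie, method = "top_snp")$snp_id, "snpA")

  zero <- tibble::tibble(snp_id = "s", effect = 0, se = 1)
  expect_error(build_weights(zero, method = "top_snp"),
               class = "multipcg_degenerate_weight_error")
})

test_that("product prediction is a centered linear map of genotypes", {
  G <- simulate_genotypes(50, 5, seed = 2)
  w0 <- tibble::tibble(snp_id = colnames(G), weight = rep(0, 5))
  expect_equal(predict_product(G, w0), rep(0, 50))

  w1 <- tibble::tibble(snp_id = colnames(G)[2], weight = 1)
  expect_equal(predict_product(G, w1), G[, 2] - mean(G[, 2]))

  w <- tibble::tibble(snp_id = colnames(G), weight = rnorm(5))
  w2 <- dplyr::mutate(w, weight = 2 * weight)
  expect_equal(predict_product(G, w2), 2 * predict_product(G, w))

  expect_error(predict_product(G, tibble::tibble(snp_id = "zzz", weight = 1)),
               "zzz", class = "multipcg_alignment_error")
})

test_that("conditional selection recovers multi-signal architectures", {
  set.seed(9)
  G <- simulate_genotypes(600, 80, seed = 9)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  y <- Gc[, 10] * 0.6 + Gc[, 40] * 0.5 + rnorm(600)
  sel <- conditional_select(G, y)
  expect_setequal(sel, colnames(G)[c(10, 40)])
  w <- conditional_weights(G, y)
  expect_setequal(w$snp_id, colnames(G)[c(10, 40)])
  expect_equal(w$weight[match(colnames(G)[10], w$snp_id)], 0.6,
               tolerance = 0.15)
  # pure noise: falls back to a single top-SNP weight
  ynull <- rnorm(600)
  wnull <- conditional_weights(G, ynull)
  expect_equal(nrow(wnull), 1L)
})

test_that("joint test equals the canonical correlation and saturates", {
  set.seed(21)
  n <- 400
  Ehat <- rnorm(n)
  Phat <- 0.4 * Ehat + rnorm(n)
  Y <- 0.5 * Ehat - 0.2 * Phat + rnorm(n)
  Y <- Y - mean(Y)
  wr <- joint_wald_individual(Y, Ehat, Phat)
  # independent oracle: stats::cancor on the same data
  cc <- stats::cancor(cbind(Y), cbind(Ehat, Phat))
  expect_equal(wr$r2_joint, cc$cor[1]^2, tolerance = 1e-8)
  expect_equal(wr$W_joint, n * wr$r2_joint / (1 - wr$r2_joint))
  expect_gte(wr$W_joint, max(wr$W_E, wr$W_P) - 1e-6)
  expect_equal(wr$rho, cor(Ehat, Phat))

  # perfect fit limit
  noise <- rnorm(n)
  wr2 <- joint_wald_individual(Ehat, Ehat, noise)
  expect_gt(wr2$r2_joint, 1 - 1e-6)
  expect_gt(wr2$W_joint, 1e5)

  # collinear instruments collapse to one degree of freedom
  wr3 <- joint_wald_individual(Y, Ehat, Ehat)
  expect_equal(wr3$df_joint, 1L)
  expect_true(wr3$rank_deficient)

  expect_error(joint_wald_individual(rep(0, n), Ehat, Phat),
               class = "multipcg_undefined_statistic_error")
})

test_that("joint statistic is central chi-square(2) under the null", {
  set.seed(31)
  n <- 1000
  reps <- 400
  W <- replicate(reps, {
    joint_wald_individual(rnorm(n), rnorm(n), rnorm(n))$W_joint
  })
  # mean of chi-square(2) is 2; MC standard error ~ 2/sqrt(reps)
  expect_equal(mean(W), 2, tolerance = 3 * 2 / sqrt(reps))
})

test_that("summary-statistics path matches its quadratic-form contract", {
  snps <- paste0("s", 1:4)
  z <- c(3, -2, 0.5, 1)
  gs <- gwas_summary(snps, z, diag(4), n = 5000)
  wE <- tibble::tibble(snp_id = "s1", weight = 1)
  wP <- tibble::tibble(snp_id = "s2", weight = 1)
  wr <- joint_wald_summary(gs, wE, wP)
  expect_equal(wr$W_joint, 3^2 + 2^2, tolerance = 1e-6)
  expect_equal(wr$df_joint, 2L)

  # identical weight vectors -> rank-deficient, stronger product kept
  wr2 <- joint_wald_summary(gs, wE, wE)
  expect_true(wr2$rank_deficient)
  expect_equal(wr2$df_joint, 1L)
  expect_equal(wr2$W_joint, wr2$W_E)

  # invariance to positive rescaling of any weight vector
  wr3 <- joint_wald_summary(gs, dplyr::mutate(wE, weight = 7 * weight), wP)
  expect_equal(wr3$W_joint, wr$W_joint, tolerance = 1e-5)
  expect_equal(wr3$z_E, wr$z_E, tolerance = 1e-9)

  bad <- gwas_summary(snps[1:2], z[1:2], diag(2), 100)
  expect_error(joint_wald_summary(bad, tibble::tibble(snp_id = "zz",
                                                      weight = 1), wP),
               class = "multipcg_alignment_error")
})

test_that("with in-sample LD the summary path reproduces the individual path", {
  set.seed(41)
  n <- 1000
  G <- simulate_genotypes(n, 40, seed = 41)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  wE <- tibble::tibble(snp_id = colnames(G)[c(3, 17)], weight = c(0.5, 0.3))
  wP <- tibble::tibble(snp_id = colnames(G)[c(3, 25)], weight = c(0.4, -0.5))
  Ehat <- predict_product(G, wE)
  Phat <- predict_product(G, wP)
  Y <- 0.08 * Ehat + 0.06 * Phat + rnorm(n)
  Y <- Y - mean(Y)
  wr_ind <- joint_wald_individual(Y, Ehat, Phat)

  scan <- marginal_scan(G, Y)
  gs <- gwas_summary(scan$snp_id, scan$z, cor(Gc), n = n)
  wr_sum <- joint_wald_summary(gs, standardize_weights(wE, G),
                               standardize_weights(wP, G))
  expect_equal(wr_sum$W_joint, wr_ind$W_joint,
               tolerance = 0.05 * wr_ind$W_joint)
  expect_equal(wr_sum$z_E, wr_ind$z_E, tolerance = 0.05 * abs(wr_ind$z_E))
  expect_equal(wr_sum$rho, wr_ind$rho, tolerance = 0.02)
})
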