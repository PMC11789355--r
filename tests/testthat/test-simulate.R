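test_that("genotype simulation honours frequencies, seeds, and LD blocks", {
  G <- simulate_genotypes(10000, 4, maf_range = c(0.5, 0.5), seed = 1)
  expect_equal(unname(colMeans(G)), rep(1, 4), tolerance = 0.05)
  expect_true(all(G %in% 0:2))

  expect_identical(simulate_genotypes(50, 10, seed = 3),
                   simulate_genotypes(50, 10, seed = 3))

  # within-block genotype correlation is monotone in the AR(1) parameter
  mean_adj_cor <- function(rho) {
    G <- simulate_genotypes(4000, 10, maf_range = c(0.2, 0.4), seed = 5,
                            block_rho = rho, block_size = 10)
    cc <- cor(G)
    mean(cc[cbind(1:9, 2:10)])
  }
  cors <- vapply(c(0.2, 0.5, 0.9), mean_adj_cor, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.5)

  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)),
               class = "multipcg_argument_error")
})

test_that("mechanism draws compose to the configured proportions", {
  set.seed(11)
  fr <- replicate(100, {
    mean(draw_mechanisms(1198, c(0.8, 0.1, 0.05, 0.05)) != "M0")
  })
  expect_equal(mean(fr), 0.2, tolerance = 0.02)
})

test_that("simulated datasets carry faithful ground truth", {
  ds <- tiny_dataset(n_genes = 40, seed = 13)
  expect_equal(nrow(ds$truth), 40)
  g <- ds$genes[[1]]
  expect_equal(dim(g$G1), c(300, 60))
  expect_false(identical(g$G1, g$G3))  # disjoint cohorts

  # null-mechanism genes have exactly zero effects and zero mediated PVE
  nulls <- dplyr::filter(ds$truth, mechanism == "M0")
  expect_true(all(nulls$gamma == 0 & nulls$delta == 0))
  expect_true(all(nulls$pve_med_E == 0 & nulls$pve_med_P == 0))
  me <- dplyr::filter(ds$truth, mechanism == "ME")
  if (nrow(me) > 0) expect_true(all(me$delta == 0 & me$gamma != 0))

  # all-null configuration
  ds0 <- tiny_dataset(n_genes = 10, seed = 14, mech_probs = c(1, 0, 0, 0))
  expect_true(all(ds0$truth$gamma == 0))
  expect_true(all(ds0$truth$pve_med_E == 0))

  # reproducibility: identical config + seed gives identical truth
  ds2 <- tiny_dataset(n_genes = 40, seed = 13)
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$genes[[5]]$Y, ds2$genes[[5]]$Y)

  expect_error(sim_config(snps_per_gene = 4),
               class = "multipcg_argument_error")
  expect_error(sim_config(mech_probs = c(0.5, 0.5, 0.2, -0.2)),
               class = "multipcg_argument_error")
})

test_that("residuals are uncorrelated across cohorts and variance decomposes", {
  ds <- tiny_dataset(n_genes = 25, seed = 17)
  n <- 300
  cors <- vapply(ds$genes, function(g) cor(g$E, g$P), numeric(1))
  # E (cohort 1) and P (cohort 2) share only genetic architecture at the
  # shared QTL; their sample correlation stays near zero on average
  expect_lt(abs(mean(cors)), 3 / sqrt(n * length(cors) / 10))

  # realized expression PVE matches its generative components
  tr <- ds$truth
  expect_true(all(tr$pve_E >= 0 & tr$pve_E < 1))
  expect_true(all(tr$pve_Y >= 0 & tr$pve_Y < 1))
})

test_that("default study conditions give realistic molecular heritability", {
  # mean expression PVE across genes over ten replicate datasets
  pves <- unlist(lapply(1:10, function(k) {
    ds <- simulate_dataset(sim_config(n_genes = 60, seed = 500 + k))
    out <- ds$truth$pve_E
    rm(ds)
    out
  }))
  expect_gt(mean(pves), 0.10)
  expect_lt(mean(pves), 0.25)
})

test_that("dataset export writes a complete plain-text directory", {
  ds <- tiny_dataset(n_genes = 2, seed = 19)
  dir <- withr::local_tempdir()
  write_sim_dataset(ds, dir)
  files <- list.files(dir)
  expect_true("truth.tsv" %in% files)
  expect_true("manifest.tsv" %in% files)
  expect_true(all(sprintf("%s_pheno.tsv", ds$truth$gene_id) %in% files))
  truth_back <- readr::read_tsv(file.path(dir, "truth.tsv"),
                                show_col_types = FALSE)
  expect_equal(truth_back$gene_id, ds$truth$gene_id)
})

test_that("benchmark reports are deterministic given the configuration", {
  cfg <- sim_config(n_genes = 40, n_per_cohort = 300, snps_per_gene = 60,
                    seed = 23)
  r1 <- run_benchmark(cfg)
  r2 <- run_benchmark(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$h_estimates, r2$h_estimates)

  # all-null dataset: power undefined (NA), false discoveries still counted
  cfg0 <- sim_config(n_genes = 30, n_per_cohort = 300, snps_per_gene = 60,
                     seed = 29, mech_probs = c(1, 0, 0, 0))
  r0 <- run_benchmark(cfg0)
  multi <- dplyr::filter(r0$summary, method == "multi")
  expect_true(is.na(multi$power))
  expect_gte(multi$n_reject, 0)
})
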