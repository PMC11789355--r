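#' Simulation configuration
#'
#' Study conditions for the multi-cohort generative model: per gene, two
#' eQTLs and two pQTLs (sharing exactly one variant) plus a distinct
#' direct-effect GWAS SNP, all edge effects drawn from `N(0, phi^2)`, a
#' causal mechanism drawn from `Multinomial(mech_probs)` over
#' (null, expression-only, protein-only, both), and residual variances 1.
#' Expression, protein, and the complex trait are observed in three disjoint
#' cohorts (multi-sample design).
#'
#' @param n_genes Number of genes (default 1198).
#' @param n_per_cohort Individuals per cohort (default 500).
#' @param snps_per_gene Synthetic cis-SNPs per gene (default 200; >= 5).
#' @param maf_range Minor-allele-frequency interval, a sub-interval of
#'   (0, 0.5\] (default `c(0.05, 0.5)`).
#' @param mech_probs Mechanism probabilities `(pi_0, pi_E, pi_P, pi_EP)`
#'   summing to 1 (default `c(0.8, 0.1, 0.05, 0.05)`).
#' @param phi Effect-size standard deviation (default 0.6).
#' @param resid_var Residual variance of E, P, and Y (default 1).
#' @param confounder Include a shared latent confounder `U` with per-gene
#'   effects on E, P, and Y drawn `N(0, phi^2)` (default `TRUE`).
#' @param pleiotropy Give every gene a distinct direct-effect GWAS SNP
#'   (`beta_Y != 0`), the stringent exclusion-restriction-violation setting
#'   (default `TRUE`).
#' @param block_rho,block_size Optional AR(1) linkage-disequilibrium blocks
#'   for the genotypes (`block_rho = 0`, independent SNPs, by default).
#' @param seed Master seed; per-gene random streams are derived from it so
#'   gene subsets are reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1198L, n_per_cohort = 500L,
                       snps_per_gene = 200L, maf_range = c(0.05, 0.5),
                       mech_probs = c(0.8, 0.1, 0.05, 0.05), phi = 0.6,
                       resid_var = 1, confounder = TRUE, pleiotropy = TRUE,
                       block_rho = 0, block_size = 10L, seed = 1L) {
  if (snps_per_gene < 5) {
    abort_arg("`snps_per_gene` must be >= 5 to place distinct causal SNPs.")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort_arg("`maf_range` must be an interval within (0, 0.5].")
  }
  if (length(mech_probs) != 4 || any(mech_probs < 0) ||
      abs(sum(mech_probs) - 1) > 1e-8) {
    abort_arg("`mech_probs` must be 4 probabilities summing to 1.")
  }
  if (phi <= 0) abort_arg("`phi` must be positive.")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_cohort = as.integer(n_per_cohort),
                 snps_per_gene = as.integer(snps_per_gene),
                 maf_range = maf_range, mech_probs = mech_probs, phi = phi,
                 resid_var = resid_var, confounder = confounder,
                 pleiotropy = pleiotropy, block_rho = block_rho,
                 block_size = as.integer(block_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype matrix
#'
#' Dosage genotypes: each SNP's minor-allele frequency is drawn uniformly
#' from `maf_range` and genotypes are `Binomial(2, maf)`. With
#' `block_rho > 0`, alleles within consecutive blocks are generated from an
#' AR(1) Gaussian copula, inducing linkage disequilibrium whose strength is
#' monotone in `block_rho`.
#'
#' @param n Individuals.
#' @param p SNPs.
#' @param maf_range Interval within (0, 0.5\].
#' @param seed Optional seed for reproducibility.
#' @param maf Optional fixed per-SNP frequencies (overrides `maf_range`).
#' @param block_rho,block_size AR(1) LD block parameters.
#' @return An `n x p` integer matrix with values in 0:2 and SNP column
#'   names.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), seed = NULL,
                               maf = NULL, block_rho = 0, block_size = 10L) {
  if (!is.null(seed)) set.seed(seed)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort_arg("`maf_range` must be an interval within (0, 0.5].")
  }
  if (is.null(maf)) maf <- runif(p, maf_range[1], maf_range[2])
  if (block_rho <= 0) {
    G <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  } else {
    # two haplotypes per individual from an AR(1) Gaussian copula
    thr <- qnorm(maf)
    hap <- function() {
      X <- matrix(rnorm(n * p), n, p)
      for (j in seq_len(p)[-1]) {
        if ((j - 1) %% block_size != 0) {
          X[, j] <- block_rho * X[, j - 1] +
            sqrt(1 - block_rho^2) * X[, j]
        }
      }
      t(t(X) < thr) + 0L
    }
    G <- hap() + hap()
  }
  storage.mode(G) <- "integer"
  colnames(G) <- sprintf("snp%04d", seq_len(p))
  G
}

#' Draw causal mechanisms for a set of genes
#'
#' @param n_genes Number of genes.
#' @param mech_probs Probabilities of `(M0, ME, MP, MEP)`.
#' @return Character vector of mechanism labels.
#' @export
draw_mechanisms <- function(n_genes, mech_probs = c(0.8, 0.1, 0.05, 0.05)) {
  if (abs(sum(mech_probs) - 1) > 1e-8 || any(mech_probs < 0)) {
    abort_arg("`mech_probs` must be 4 probabilities summing to 1.")
  }
  sample(c("M0", "ME", "MP", "MEP"), n_genes, replace = TRUE,
         prob = mech_probs)
}

simulate_gene <- function(cfg, gene_id, mechanism, gene_seed) {
  set.seed(gene_seed)
  n <- cfg$n_per_cohort
  p <- cfg$snps_per_gene
  maf <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
  G1 <- simulate_genotypes(n, p, maf = maf, block_rho = cfg$block_rho,
                           block_size = cfg$block_size)
  G2 <- simulate_genotypes(n, p, maf = maf, block_rho = cfg$block_rho,
                           block_size = cfg$block_size)
  G3 <- simulate_genotypes(n, p, maf = maf, block_rho = cfg$block_rho,
                           block_size = cfg$block_size)
  snp_ids <- colnames(G1)

  causal <- sample.int(p, 4L)  # shared eQTL/pQTL, extra eQTL, extra pQTL, GWAS
  eqtl <- causal[c(1L, 2L)]
  pqtl <- causal[c(1L, 3L)]
  gwas_snp <- causal[4L]

  phi <- cfg$phi
  beta_E <- numeric(p); beta_E[eqtl] <- rnorm(2L, 0, phi)
  beta_P <- numeric(p); beta_P[pqtl] <- rnorm(2L, 0, phi)
  beta_Y <- numeric(p)
  if (cfg$pleiotropy) beta_Y[gwas_snp] <- rnorm(1L, 0, phi)

  gamma <- if (mechanism %in% c("ME", "MEP")) rnorm(1L, 0, phi) else 0
  delta <- if (mechanism %in% c("MP", "MEP")) rnorm(1L, 0, phi) else 0

  theta <- if (cfg$confounder) rnorm(3L, 0, phi) else c(0, 0, 0)
  sdr <- sqrt(cfg$resid_var)

  gE1 <- drop(G1 %*% beta_E)
  E <- gE1 + theta[1] * rnorm(n) + rnorm(n, 0, sdr)
  gP2 <- drop(G2 %*% beta_P)
  P <- gP2 + theta[2] * rnorm(n) + rnorm(n, 0, sdr)

  U3 <- rnorm(n)
  E3 <- drop(G3 %*% beta_E) + theta[1] * U3 + rnorm(n, 0, sdr)
  P3 <- drop(G3 %*% beta_P) + theta[2] * U3 + rnorm(n, 0, sdr)
  Y <- drop(G3 %*% beta_Y) + gamma * E3 + delta * P3 + theta[3] * U3 +
    rnorm(n, 0, sdr)

  med_E <- gamma * drop(G3 %*% beta_E)
  med_P <- delta * drop(G3 %*% beta_P)
  vY <- var(Y)
  truth <- tibble::tibble(
    gene_id = gene_id, mechanism = mechanism, gamma = gamma, delta = delta,
    eqtl_snps = paste(snp_ids[eqtl], collapse = ","),
    pqtl_snps = paste(snp_ids[pqtl], collapse = ","),
    gwas_snp = snp_ids[gwas_snp],
    pve_E = var(gE1) / var(E), pve_P = var(gP2) / var(P),
    pve_Y = var(drop(G3 %*% beta_Y) + med_E + med_P) / vY,
    pve_med_E = if (gamma == 0) 0 else var(med_E) / vY,
    pve_med_P = if (delta == 0) 0 else var(med_P) / vY)

  list(gene_id = gene_id, G1 = G1, G2 = G2, G3 = G3, E = E, P = P, Y = Y,
       truth = truth)
}

#' Simulate a multi-cohort dataset with ground-truth mechanisms
#'
#' Generates, for every gene, genotypes for three disjoint cohorts and the
#' molecular/complex phenotypes under the structural model: expression and
#' protein each receive effects from their (partially shared) causal QTLs
#' and the latent confounder; the complex trait receives the mechanism-
#' dependent product effects, a direct (pleiotropic) SNP effect, and the
#' confounder. Mechanism labels, causal-SNP placements, true effects, and
#' realized proportions of variance explained (PVE) are recorded.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_dataset`: a list with `config`, `genes`
#'   (per-gene list of genotype matrices `G1`, `G2`, `G3` and phenotypes
#'   `E`, `P`, `Y`), and `truth` (tibble of per-gene ground truth).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  mech <- draw_mechanisms(cfg$n_genes, cfg$mech_probs)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_genes)
  ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  genes <- purrr::pmap(list(ids, mech, gene_seeds), function(id, m, s) {
    simulate_gene(cfg, id, m, s)
  })
  truth <- dplyr::bind_rows(purrr::map(genes, "truth"))
  structure(list(config = cfg, genes = genes, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d genes x %d SNPs, 3 cohorts of %d (seed %d)\n",
    x$config$n_genes, x$config$snps_per_gene, x$config$n_per_cohort,
    x$config$seed))
  print(table(x$truth$mechanism))
  invisible(x)
}

#' Write a simulated dataset to a directory of delimited files
#'
#' One tab-separated genotype file per gene and cohort, one phenotype file
#' per gene, a per-gene truth table, and a manifest.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in ds$genes) {
    for (co in 1:3) {
      G <- g[[paste0("G", co)]]
      readr::write_tsv(tibble::as_tibble(G),
                       file.path(dir, sprintf("%s_G%d.tsv", g$gene_id, co)),
                       progress = FALSE)
    }
    readr::write_tsv(
      tibble::tibble(E = g$E, P = g$P, Y = g$Y),
      file.path(dir, sprintf("%s_pheno.tsv", g$gene_id)), progress = FALSE)
  }
  readr::write_tsv(ds$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  manifest <- tibble::tibble(
    key = c("n_genes", "n_per_cohort", "snps_per_gene", "phi", "seed"),
    value = c(ds$config$n_genes, ds$config$n_per_cohort,
              ds$config$snps_per_gene, ds$config$phi, ds$config$seed))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}
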