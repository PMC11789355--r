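#' Empirical-Bayes putative-causal-gene fit
#'
#' The core inference step: given per-gene model Bayes factors and
#' colocalization probabilities, estimates the global prior parameters
#' (`pi` by EM on the two-group mixture; the mechanism proportions
#' `h = (h_E, h_P, h_EP)` by EM across genes), computes each gene's
#' probability of putative causality (GPPC), its local false discovery rate,
#' Bayesian-FDR rejection flags, posterior mechanism-model probabilities,
#' and gene-product relevance probabilities.
#'
#' @param genes Tibble with one row per gene and columns `gene_id`,
#'   `log_bf_E`, `log_bf_P`, `log_bf_EP`, `coloc_E`, `coloc_P` (as produced
#'   by [analyze_dataset()] or by combining [gene_bayes_factors()] with
#'   colocalization output).
#' @param alpha Target Bayesian FDR level (default 0.05).
#' @param prior_shape `"linear"` (default) or `"step"` prior function.
#' @param threshold Colocalization truncation threshold (default 0.05).
#' @param combine Colocalization combination rule (default `"max"`).
#' @param pi Optional fixed mixture proportion; if `NULL` (default) it is
#'   estimated by [estimate_pi()].
#' @param gppc_mixture `"estimated_h"` (default) computes the overall Bayes
#'   factor entering the GPPC with the EM-estimated mechanism proportions,
#'   so that `gppc = 1 - post_M0` and relevance probabilities never exceed
#'   the GPPC; `"uniform"` uses the uniform 1/3 mixture (the two-stage
#'   ordering in which the GPPC predates the mechanism EM).
#' @param tau_grid Variance-ratio grid for the Bayes factors already formed;
#'   kept for provenance in the returned object.
#' @param h_pseudo_count Symmetric Dirichlet pseudo-count stabilizing the
#'   mechanism-proportion EM (default 1; see [em_estimate_h()]). Set to 0
#'   for the pure maximum-likelihood estimate.
#' @return An object of class `pcg_fit`: a list with `genes` (per-gene
#'   tibble including `gppc`, `lfdr`, `fdr_reject`, `post_M0` ...
#'   `post_MEP`, `relevance_E`, `relevance_P`), `pi`, `h`, `alpha`, and fit
#'   metadata. Use [tidy.pcg_fit()], [glance.pcg_fit()], or
#'   [autoplot.pcg_fit()].
#' @export
pcg_fit <- function(genes, alpha = 0.05,
                    prior_shape = c("linear", "step"), threshold = 0.05,
                    combine = c("max", "one_minus_prod"), pi = NULL,
                    gppc_mixture = c("estimated_h", "uniform"),
                    tau_grid = c(1, 2, 4, 8, 16, 32, 64, 128),
                    h_pseudo_count = 1) {
  prior_shape <- match.arg(prior_shape)
  combine <- match.arg(combine)
  gppc_mixture <- match.arg(gppc_mixture)
  required <- c("gene_id", "log_bf_E", "log_bf_P", "log_bf_EP",
                "coloc_E", "coloc_P")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    abort_format(sprintf("`genes` is missing column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  genes <- dplyr::arrange(genes, .data$gene_id)
  f <- prior_f(genes$coloc_E, genes$coloc_P, shape = prior_shape,
               threshold = threshold, combine = combine)
  lbf_mat <- cbind(genes$log_bf_E, genes$log_bf_P, genes$log_bf_EP)
  lbf_uniform <- row_logsumexp(lbf_mat) - log(3)

  if (is.null(pi)) {
    pi_fit <- estimate_pi(lbf_uniform, f)
    pi <- pi_fit$pi
  } else {
    check_prob(pi, "pi")
    pi_fit <- list(pi = pi, n_iter = 0L, converged = NA)
  }
  prior <- pi * f

  h_fit <- NULL
  h <- c(E = 1, P = 1, EP = 1) / 3
  if (sum(prior > 0) >= 2) {
    h_fit <- em_estimate_h(
      tibble::tibble(gene_id = genes$gene_id,
                     log_bf_E = genes$log_bf_E,
                     log_bf_P = genes$log_bf_P,
                     log_bf_EP = genes$log_bf_EP),
      prior_values = prior, pseudo_count = h_pseudo_count)
    h <- h_fit$h
  }

  mix <- if (gppc_mixture == "estimated_h") h else c(E = 1, P = 1, EP = 1) / 3
  lmix <- ifelse(mix > 0, log(mix), -Inf)
  log_bf_overall <- row_logsumexp(sweep(lbf_mat, 2L, lmix, "+"))
  gppc <- compute_gppc(prior, log_bf_overall)
  lfdr <- 1 - gppc
  reject <- bayesian_fdr_control(lfdr, alpha)

  post <- posterior_model_probs(genes$log_bf_E, genes$log_bf_P,
                                genes$log_bf_EP, prior, h)
  post <- relevance_probs(post)

  out <- dplyr::bind_cols(
    genes,
    tibble::tibble(f = f, prior = prior,
                   log_bf_overall = log_bf_overall,
                   gppc = gppc, lfdr = lfdr, fdr_reject = reject),
    post)
  structure(list(genes = out, pi = pi, h = h, alpha = alpha,
                 prior_shape = prior_shape, threshold = threshold,
                 combine = combine, gppc_mixture = gppc_mixture,
                 tau_grid = tau_grid, pi_fit = pi_fit, h_fit = h_fit),
            class = "pcg_fit")
}

#' @export
print.pcg_fit <- function(x, ...) {
  cat(sprintf(
    "<pcg_fit> %d genes | pi = %.3f | h = (E %.3f, P %.3f, E+P %.3f)\n",
    nrow(x$genes), x$pi, x$h[["E"]], x$h[["P"]], x$h[["EP"]]))
  cat(sprintf("  %d gene(s) rejected at Bayesian FDR %.0f%%\n",
              sum(x$genes$fdr_reject), 100 * x$alpha))
  invisible(x)
}

#' @describeIn pcg_fit Per-gene results as a tibble.
#' @param x A `pcg_fit`.
#' @param ... Unused.
#' @method tidy pcg_fit
#' @export
tidy.pcg_fit <- function(x, ...) {
  x$genes
}

#' @describeIn pcg_fit One-row model-level summary (pi, h, rejections).
#' @method glance pcg_fit
#' @export
glance.pcg_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$genes), pi = x$pi,
                 h_E = x$h[["E"]], h_P = x$h[["P"]], h_EP = x$h[["EP"]],
                 alpha = x$alpha, n_reject = sum(x$genes$fdr_reject),
                 pi_converged = isTRUE(x$pi_fit$converged),
                 h_converged = isTRUE(x$h_fit$converged))
}

#' Single-product empirical-Bayes fit
#'
#' The single-molecular-trait analogue of [pcg_fit()] (an expression-only or
#' protein-only analysis): the prior uses only that product's
#' colocalization probability and the Bayes factor is the product's 1-df
#' shrinkage Bayes factor. Used as a power/FDR comparator in the benchmark.
#'
#' @inheritParams pcg_fit
#' @param product `"E"` or `"P"`.
#' @return A list with the per-gene tibble (`gene_id`, `gppc`, `lfdr`,
#'   `fdr_reject`), and the estimated `pi`.
#' @export
single_product_fit <- function(genes, product = c("E", "P"), alpha = 0.05,
                               prior_shape = c("linear", "step"),
                               threshold = 0.05) {
  product <- match.arg(product)
  prior_shape <- match.arg(prior_shape)
  genes <- dplyr::arrange(genes, .data$gene_id)
  p_coloc <- genes[[paste0("coloc_", product)]]
  wcol <- paste0("W_", product)
  lbf <- if (wcol %in% names(genes)) {
    wald_to_log_bf(genes[[wcol]], 1L)
  } else {
    genes[[paste0("log_bf_", product)]]
  }
  f <- prior_f(p_coloc, 0 * p_coloc, shape = prior_shape,
               threshold = threshold, combine = "max")
  pi_fit <- withCallingHandlers(
    estimate_pi(lbf, f),
    warning = function(w) invokeRestart("muffleWarning"))
  prior <- pi_fit$pi * f
  gppc <- compute_gppc(prior, lbf)
  lfdr <- 1 - gppc
  list(genes = tibble::tibble(gene_id = genes$gene_id, gppc = gppc,
                              lfdr = lfdr,
                              fdr_reject = bayesian_fdr_control(lfdr, alpha)),
       pi = pi_fit$pi, product = product, alpha = alpha)
}

#' Per-gene evidence extraction from a simulated dataset
#'
#' Runs the full evidence pipeline on each gene of a [simulate_dataset()]
#' result: molecular-QTL scans in the two molecular cohorts, instrument
#' weight construction, single-causal-variant fine-mapping and
#' colocalization against the GWAS scan, and the joint association test in
#' the GWAS cohort (individual-level or summary-statistics path).
#'
#' Colocalization is evaluated over the molecular-QTL candidate SNP set
#' (the union of both products' conditional selections), asking whether the
#' GWAS signal overlaps the gene's QTL signals, while every SNP keeps its
#' genome-wide prior `1 / (n_snps + 1)`; restricting the configuration
#' space to candidates approximates signal-level colocalization without
#' letting unrelated (e.g., purely pleiotropic) GWAS signals absorb the
#' posterior mass, and the genome-wide prior keeps chance associations at
#' null genes from colocalizing.
#'
#' @param ds A `sim_dataset` from [simulate_dataset()].
#' @param mode `"individual"` (default) regresses the GWAS trait on the
#'   predicted products; `"summary"` uses per-SNP GWAS z-scores with the
#'   in-sample LD matrix and standardized weights.
#' @param weight_method `"conditional"` (default) builds multi-SNP forward
#'   stepwise weights via [conditional_weights()] on the shared candidate
#'   set; `"pip_weighted"` and `"top_snp"` are passed to [build_weights()].
#' @param shrink_grid Approximate-Bayes-factor shrinkage grid; see
#'   [snp_log_abf()].
#' @param prior_per_snp Per-SNP causal prior for fine-mapping;
#'   `NULL` (default) uses `1 / (n_snps + 1)`.
#' @param tau_grid Bayes-factor variance-ratio grid (`NULL` = method
#'   default, see [gene_bayes_factors()]).
#' @param leak Cross-product leak prior variance; see [model_log_bfs()].
#' @return A tibble with one row per gene: `gene_id`, `coloc_E`, `coloc_P`,
#'   `W_E`, `W_P`, `W_joint`, `df_joint`, `r2_joint`, `z_E`, `z_P`, `rho`,
#'   `rank_deficient`, `log_bf_E`, `log_bf_P`, `log_bf_EP`, ready for
#'   [pcg_fit()].
#' @export
analyze_dataset <- function(ds, mode = c("individual", "summary"),
                            weight_method = c("conditional", "pip_weighted",
                                              "top_snp"),
                            shrink_grid = c(0.5, 0.8, 0.9),
                            prior_per_snp = NULL,
                            tau_grid = NULL, leak = 2) {
  mode <- match.arg(mode)
  weight_method <- match.arg(weight_method)
  stopifnot(inherits(ds, "sim_dataset"))
  rows <- purrr::map(ds$genes, function(g) {
    analyze_gene(g, mode = mode, weight_method = weight_method,
                 shrink_grid = shrink_grid, prior_per_snp = prior_per_snp)
  })
  wald_tbl <- dplyr::bind_rows(rows)
  bf <- gene_bayes_factors(wald_tbl, tau_grid = tau_grid, leak = leak)
  dplyr::left_join(wald_tbl, dplyr::select(bf, -"log_bf_overall"),
                   by = "gene_id")
}

analyze_gene <- function(g, mode, weight_method, shrink_grid,
                         prior_per_snp) {
  p <- ncol(g$G1)
  if (is.null(prior_per_snp)) prior_per_snp <- 1 / (p + 1)
  scan_E <- marginal_scan(g$G1, g$E)
  scan_P <- marginal_scan(g$G2, g$P)
  scan_Y <- marginal_scan(g$G3, g$Y)

  if (weight_method == "conditional") {
    # joint candidate set: union of both products' conditional selections,
    # so a QTL detected in either product enters both instruments and
    # cross-product signal leakage is carried by the instrument correlation
    sel <- union(conditional_select(g$G1, g$E),
                 conditional_select(g$G2, g$P))
    if (length(sel) == 0) {
      wE <- build_weights(scan_E, method = "top_snp", product = "E")
      wP <- build_weights(scan_P, method = "top_snp", product = "P")
    } else {
      wE <- conditional_weights(g$G1, g$E, product = "E", snps = sel)
      wP <- conditional_weights(g$G2, g$P, product = "P", snps = sel)
    }
  } else {
    fm_full_E <- finemap_single_causal(snp_log_abf(scan_E$z, shrink_grid),
                                       prior_per_snp, scan_E$snp_id)
    fm_full_P <- finemap_single_causal(snp_log_abf(scan_P$z, shrink_grid),
                                       prior_per_snp, scan_P$snp_id)
    wE <- build_weights(scan_E, method = weight_method,
                        pip = fm_full_E$pip, product = "E")
    wP <- build_weights(scan_P, method = weight_method,
                        pip = fm_full_P$pip, product = "P")
  }

  # colocalization over the molecular-QTL candidate configuration space,
  # with each SNP keeping its genome-wide causal prior
  cand <- sort(union(wE$snp_id, wP$snp_id))
  idx <- match(cand, scan_E$snp_id)
  fm_E <- finemap_single_causal(snp_log_abf(scan_E$z[idx], shrink_grid),
                                prior_per_snp, cand)
  fm_P <- finemap_single_causal(snp_log_abf(scan_P$z[idx], shrink_grid),
                                prior_per_snp, cand)
  fm_Y <- finemap_single_causal(snp_log_abf(scan_Y$z[idx], shrink_grid),
                                prior_per_snp, cand)
  coloc_E <- gene_coloc_prob(fm_E, fm_Y)
  coloc_P <- gene_coloc_prob(fm_P, fm_Y)

  if (mode == "individual") {
    Ehat <- predict_product(g$G3, wE)
    Phat <- predict_product(g$G3, wP)
    wr <- joint_wald_individual(g$Y - mean(g$Y), Ehat, Phat)
  } else {
    R <- suppressWarnings(cor(g$G3))
    keep <- is.finite(diag(R))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    gs <- gwas_summary(scan_Y$snp_id, scan_Y$z, R, length(g$Y))
    wr <- joint_wald_summary(gs, standardize_weights(wE, g$G3),
                             standardize_weights(wP, g$G3))
  }
  dplyr::bind_cols(tibble::tibble(gene_id = g$gene_id,
                                  coloc_E = coloc_E, coloc_P = coloc_P),
                   tidy(wr)[, c("W_E", "W_P", "W_joint", "df_joint",
                                "r2_joint", "z_E", "z_P", "rho",
                                "rank_deficient")])
}
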