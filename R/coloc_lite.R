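#' Approximate Bayes factor for a single-SNP association
#'
#' Wakefield-style asymptotic Bayes factor computed from a z-score, averaged
#' over a grid of shrinkage ratios `r = W/(V + W)` (prior variance over
#' prior-plus-sampling variance). For one grid value the Bayes factor is
#' `sqrt(1 - r) * exp(z^2 * r / 2)`; the returned value is the log of the
#' uniform grid average, computed stably in log space.
#'
#' @param z Numeric vector of association z-scores.
#' @param shrink_grid Shrinkage ratios, each in (0, 1).
#' @return Log approximate Bayes factor(s), same length as `z`; finite for
#'   finite `z` and strictly increasing in `|z|`.
#' @export
#' @examples
#' snp_log_abf(0, shrink_grid = 0.5)  # log(sqrt(0.5))
snp_log_abf <- function(z, shrink_grid = c(0.5, 0.8, 0.9)) {
  if (length(shrink_grid) == 0) {
    abort_arg("`shrink_grid` must be non-empty.")
  }
  if (any(shrink_grid <= 0 | shrink_grid >= 1)) {
    abort_arg("`shrink_grid` values must lie strictly in (0, 1).")
  }
  # terms[i, j] = 0.5 * log(1 - r_j) + z_i^2 * r_j / 2
  terms <- outer(z^2 / 2, shrink_grid) +
    rep(0.5 * log1p(-shrink_grid), each = length(z))
  if (length(z) == 1L) {
    logmeanexp(drop(terms))
  } else {
    row_logsumexp(terms) - log(length(shrink_grid))
  }
}

#' Single-causal-variant fine-mapping from log Bayes factors
#'
#' Posterior inclusion probabilities under the assumption of at most one
#' causal variant in the region: configuration `j` (SNP `j` causal) has prior
#' mass `prior_per_snp` and likelihood `exp(log_abf[j])`; the null
#' configuration takes the remaining prior mass `1 - k * prior_per_snp`.
#'
#' @param log_abf Numeric vector of per-SNP log approximate Bayes factors.
#' @param prior_per_snp Prior probability that a given SNP is the causal one;
#'   defaults to `1 / (k + 1)` for `k` SNPs so the null retains mass.
#' @param snp_ids Optional SNP identifiers.
#' @return An object of class `finemap_result`: a tibble with columns
#'   `snp_id` and `pip`, plus attributes `null_prob` (posterior probability
#'   of no causal variant) and `includes_null = TRUE`.
#' @export
finemap_single_causal <- function(log_abf,
                                  prior_per_snp = 1 / (length(log_abf) + 1),
                                  snp_ids = NULL) {
  k <- length(log_abf)
  if (k == 0) abort_arg("`log_abf` must be non-empty.")
  if (prior_per_snp <= 0 || prior_per_snp * k > 1 + 1e-12) {
    abort_arg("`prior_per_snp` * length(log_abf) must lie in (0, 1].")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(k))
  null_mass <- max(0, 1 - prior_per_snp * k)
  log_terms <- log(prior_per_snp) + log_abf
  log_null <- if (null_mass > 0) log(null_mass) else -Inf
  log_denom <- logsumexp(c(log_terms, log_null))
  pip <- exp(log_terms - log_denom)
  out <- tibble::tibble(snp_id = as.character(snp_ids), pip = pip)
  structure(out,
            null_prob = exp(log_null - log_denom),
            includes_null = TRUE,
            class = c("finemap_result", class(out)))
}

#' Gene-level colocalization probability
#'
#' Probability that the molecular QTL and the GWAS signal share at least one
#' causal variant, under an independence approximation across SNPs:
#' `1 - prod_j (1 - pip_qtl[j] * pip_gwas[j])`.
#'
#' @param fm_qtl,fm_gwas [finemap_single_causal()] results over the same SNP
#'   set (any order; aligned by `snp_id`).
#' @return A probability in \[0, 1\]; 0 whenever the supports are disjoint.
#' @export
#' @examples
#' fq <- finemap_single_causal(c(10, 0), snp_ids = c("a", "b"))
#' fg <- finemap_single_causal(c(10, 0), snp_ids = c("a", "b"))
#' gene_coloc_prob(fq, fg)
gene_coloc_prob <- function(fm_qtl, fm_gwas) {
  if (!setequal(fm_qtl$snp_id, fm_gwas$snp_id) ||
      nrow(fm_qtl) != nrow(fm_gwas)) {
    abort_alignment("Fine-mapping results must cover identical SNP sets.")
  }
  g <- fm_gwas$pip[match(fm_qtl$snp_id, fm_gwas$snp_id)]
  joint <- pmin(pmax(fm_qtl$pip * g, 0), 1)
  # 1 - prod(1 - x) via log1p for accuracy with many small terms
  -expm1(sum(log1p(-joint)))
}

#' Colocalization probability from two z-score vectors
#'
#' Convenience wrapper: fine-maps each trait under the single-causal-variant
#' model and returns the gene-level colocalization probability. No LD matrix
#' is needed (the single-causal model integrates over configurations, not
#' over LD).
#'
#' @param z_qtl,z_gwas Per-SNP z-scores for the molecular QTL scan and the
#'   GWAS scan, aligned to `snp_ids`.
#' @param snp_ids Optional shared SNP identifiers.
#' @param shrink_grid Passed to [snp_log_abf()].
#' @param prior_per_snp Passed to [finemap_single_causal()].
#' @return A probability in \[0, 1\].
#' @export
coloc_scan <- function(z_qtl, z_gwas, snp_ids = NULL,
                       shrink_grid = c(0.5, 0.8, 0.9),
                       prior_per_snp = 1 / (length(z_qtl) + 1)) {
  if (length(z_qtl) != length(z_gwas)) {
    abort_alignment("`z_qtl` and `z_gwas` must have equal length.")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_along(z_qtl))
  fm_q <- finemap_single_causal(snp_log_abf(z_qtl, shrink_grid),
                                prior_per_snp, snp_ids)
  fm_g <- finemap_single_causal(snp_log_abf(z_gwas, shrink_grid),
                                prior_per_snp, snp_ids)
  gene_coloc_prob(fm_q, fm_g)
}
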