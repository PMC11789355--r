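#' Aggregate gene probabilities of putative causality across traits
#'
#' The probability that a gene is putatively causal for at least one of a
#' collection of traits: `1 - prod_i (1 - GPPC_i)`. Monotone in each input,
#' permutation-invariant, and never below the largest input.
#'
#' @param gppcs Vector of per-trait gene probabilities of putative
#'   causality, each in \[0, 1\]. Empty input returns 0.
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' aggregate_gppc(c(0.5, 0.5))  # 0.75
aggregate_gppc <- function(gppcs) {
  if (length(gppcs) == 0) return(0)
  check_prob(gppcs, "gppcs")
  -expm1(sum(log1p(-gppcs)))
}

#' Aggregate gene probabilities within a long table
#'
#' @param tbl Tibble with columns `gene_id` and `gppc` (one row per gene x
#'   trait).
#' @return A tibble with one row per gene: `gene_id`, `agg_prob`.
#' @export
aggregate_gene_probs <- function(tbl) {
  stopifnot(all(c("gene_id", "gppc") %in% names(tbl)))
  tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(agg_prob = aggregate_gppc(.data$gppc),
                     .groups = "drop")
}

#' Gene-set enrichment from probabilistic gene labels
#'
#' Estimates the enrichment (log odds ratio) of putatively causal genes in
#' a gene set from per-gene causal probabilities, without thresholding them
#' into hard calls. The model is
#' `Pr(causal_i) = logistic(alpha0 + alpha1 * d_i)` with `d_i` the set
#' membership indicator; the supplied probabilities are treated as
#' posterior causal labels and the expected complete-data log-likelihood is
#' maximized by iteratively reweighted least squares (a soft-label EM whose
#' E-step is the identity). The 95% confidence interval is Wald-type, from
#' the observed information.
#'
#' @param agg_probs Tibble with columns `gene_id` and `agg_prob` (e.g. from
#'   [aggregate_gene_probs()]); the gene universe is every row.
#' @param gene_set Character vector of member gene ids; must intersect the
#'   universe, and non-members must also be present.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate` (log odds ratio `alpha1`),
#'   `std_error`, `conf_low`, `conf_high`, `n_set`, `n_universe`,
#'   `degenerate` (flag set when all probabilities are 0 or all are 1, in
#'   which case the estimate is `NA`).
#' @export
estimate_enrichment <- function(agg_probs, gene_set, conf_level = 0.95) {
  stopifnot(all(c("gene_id", "agg_prob") %in% names(agg_probs)))
  check_prob(agg_probs$agg_prob, "agg_prob")
  d <- as.numeric(agg_probs$gene_id %in% gene_set)
  if (sum(d) == 0) {
    abort("`gene_set` shares no genes with the analyzed universe.",
          class = "multipcg_estimation_error")
  }
  if (all(d == 1)) {
    abort("Need both annotated and unannotated genes in the universe.",
          class = "multipcg_estimation_error")
  }
  t_i <- agg_probs$agg_prob
  if (all(t_i == 0) || all(t_i == 1)) {
    return(tibble::tibble(estimate = NA_real_, std_error = NA_real_,
                          conf_low = NA_real_, conf_high = NA_real_,
                          n_set = sum(d), n_universe = length(d),
                          degenerate = TRUE))
  }
  # soft-label logistic likelihood, maximized by IRLS
  X <- cbind(1, d)
  beta <- c(0, 0)
  for (iter in 1:100) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zwork <- eta + (t_i - mu) / w
    fit <- stats::lm.wfit(X, zwork, w)
    beta_new <- coef(fit)
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))[2]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(estimate = unname(beta[2]), std_error = unname(se),
                 conf_low = unname(beta[2] - zq * se),
                 conf_high = unname(beta[2] + zq * se),
                 n_set = sum(d), n_universe = length(d),
                 degenerate = FALSE)
}

#' Enrichment across a collection of gene sets
#'
#' Applies [estimate_enrichment()] to each term of an annotation, keeping
#' only terms for which at least one annotated gene has a nonzero
#' aggregated probability.
#'
#' @param agg_probs Tibble with `gene_id`, `agg_prob`.
#' @param annotations Named list of character vectors (term -> gene ids).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per retained term, ordered by decreasing
#'   `estimate`, with a `significant` flag (CI excluding 0).
#' @export
enrichment_scan <- function(agg_probs, annotations, conf_level = 0.95) {
  keep <- purrr::map_lgl(annotations, function(gs) {
    hits <- agg_probs$agg_prob[agg_probs$gene_id %in% gs]
    length(hits) > 0 && any(hits > 0) && any(!agg_probs$gene_id %in% gs)
  })
  res <- purrr::imap(annotations[keep], function(gs, term) {
    dplyr::mutate(estimate_enrichment(agg_probs, gs, conf_level),
                  term = term, .before = 1)
  })
  dplyr::arrange(dplyr::bind_rows(res), dplyr::desc(.data$estimate))
}
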