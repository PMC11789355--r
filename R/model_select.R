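#' Enumerate mechanism models for a set of gene products
#'
#' The model space for `p` gene products consists of the null model plus all
#' `2^p - 1` non-empty product subsets. Enumeration is supported for
#' `p <= 4`; the combinatorial growth beyond that makes exhaustive model
#' selection impractical and is refused with an error.
#'
#' @param products Character vector of product labels (e.g. `c("E", "P")`).
#' @return A list of character vectors, one per non-null model, in
#'   a fixed order (subset size, then lexicographic).
#' @export
product_models <- function(products) {
  p <- length(products)
  if (p < 1) abort_arg("Need at least one gene product.")
  if (p > 4) {
    abort_arg(paste0(
      "Model enumeration supports at most 4 gene products (",
      2^p - 1, " non-null models for p = ", p, " is impractical)."))
  }
  products <- sort(products)
  subsets <- list()
  for (size in seq_len(p)) {
    combos <- utils::combn(products, size, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  subsets
}

check_simplex <- function(h, k, tol = 1e-8) {
  if (length(h) != k || any(h < -tol) || abs(sum(h) - 1) > tol) {
    abort_arg(sprintf("`h` must be a %d-simplex point (non-negative, sum 1).",
                      k))
  }
  pmax(h, 0) / sum(pmax(h, 0))
}

#' Estimate mechanism proportions (h) across genes by EM
#'
#' Maximum-likelihood estimate of the conditional prior proportions of the
#' non-null mechanism models, `h = (h_E, h_P, h_EP)` for two products (or
#' the general subset models for up to four products), pooling all
#' candidate genes. The marginal likelihood per gene is
#' `(1 - pi f_i) + pi f_i * sum_m h_m BF_{i,m}`; the E-step computes model
#' responsibilities within the non-null block and the M-step averages them
#' weighted by each gene's posterior non-null probability. The observed
#' log-likelihood is non-decreasing every iteration.
#'
#' @param log_bf A matrix (genes x models) of log Bayes factors, or a tibble
#'   with a `gene_id` column and one `log_bf_*` column per model (e.g.
#'   `log_bf_E`, `log_bf_P`, `log_bf_EP`). Genes are processed in
#'   `gene_id` order so results do not depend on input row order.
#' @param prior_values Per-gene prior probabilities `pi * f_i`; at least two
#'   genes must have a positive value.
#' @param init Starting simplex point (default uniform).
#' @param tol Convergence tolerance on `max |delta h|` (default 1e-8).
#' @param max_iter Iteration cap (default 5000).
#' @param pseudo_count Symmetric Dirichlet pseudo-count added to each
#'   model's expected count in the M-step (default 0 = maximum likelihood).
#'   A small positive value (a few pseudo-genes) gives the posterior-mode
#'   estimate under a `Dirichlet(1 + pseudo_count)` prior, stabilizing the
#'   estimate away from simplex corners when few genes are informative.
#' @return A list with `h` (named simplex estimate), `n_iter`, `converged`,
#'   and `log_lik` (trace of the maximized objective: the observed
#'   log-likelihood, plus the Dirichlet log-prior when `pseudo_count > 0`).
#' @export
em_estimate_h <- function(log_bf, prior_values, init = NULL, tol = 1e-8,
                          max_iter = 5000L, pseudo_count = 0) {
  if (is.data.frame(log_bf)) {
    cols <- grep("^log_bf_", names(log_bf), value = TRUE)
    cols <- setdiff(cols, "log_bf_overall")
    if ("gene_id" %in% names(log_bf)) {
      ord <- order(log_bf$gene_id)
      log_bf <- log_bf[ord, , drop = FALSE]
      prior_values <- prior_values[ord]
    }
    lbf <- as.matrix(log_bf[, cols, drop = FALSE])
    colnames(lbf) <- sub("^log_bf_", "", cols)
  } else {
    lbf <- as.matrix(log_bf)
    if (is.null(colnames(lbf))) {
      colnames(lbf) <- paste0("m", seq_len(ncol(lbf)))
    }
  }
  k <- ncol(lbf)
  if (k > 15) abort_arg("At most 4 products (15 non-null models) supported.")
  if (length(prior_values) != nrow(lbf)) {
    abort_alignment("`prior_values` must align with the Bayes factor rows.")
  }
  check_prob(prior_values, "prior_values")
  pos <- prior_values > 0
  if (sum(pos) < 2) {
    abort("Need at least 2 genes with positive prior value to estimate h.",
          class = "multipcg_estimation_error")
  }
  lbf <- lbf[pos, , drop = FALSE]
  pf <- prior_values[pos]
  if (pseudo_count < 0) abort_arg("`pseudo_count` must be non-negative.")
  h <- if (is.null(init)) rep(1 / k, k) else check_simplex(init, k)
  loglik <- function(h) {
    lmix <- row_logsumexp(sweep(lbf, 2L, log(h), "+"))
    a <- log(pf) + lmix
    b <- log1p(-pf)
    m <- pmax(a, b)
    ll <- sum(m + log(exp(a - m) + exp(b - m)))
    if (pseudo_count > 0) ll <- ll + pseudo_count * sum(log(pmax(h, 1e-300)))
    ll
  }
  ll_trace <- loglik(h)
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    lh <- ifelse(h > 0, log(h), -Inf)
    lterm <- sweep(lbf, 2L, lh, "+")
    lmix <- row_logsumexp(lterm)
    # responsibilities within the non-null block
    r <- exp(lterm - lmix)
    r[!is.finite(lmix), ] <- 1 / k
    # posterior non-null probability per gene
    q <- posterior_from_log_bf(pf, lmix)
    wsum <- colSums(q * r) + pseudo_count
    if (sum(wsum) <= 0) break
    h_new <- wsum / sum(wsum)
    ll_new <- loglik(h_new)
    if (ll_new < utils::tail(ll_trace, 1L) - 1e-8) {
      warn("EM log-likelihood decreased; stopping early.")
      break
    }
    delta <- max(abs(h_new - h))
    h <- h_new
    ll_trace <- c(ll_trace, ll_new)
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  names(h) <- colnames(lbf)
  list(h = h, n_iter = n_iter, converged = converged, log_lik = ll_trace)
}

#' Posterior mechanism-model probabilities for one or more genes
#'
#' Bayes-rule combination of the composite prior, the conditional mechanism
#' proportions `h`, and the per-model Bayes factors:
#' `post_M0 prop (1 - pi f)` and `post_Mm prop pi f * h_m * BF_m`,
#' normalized to sum to one.
#'
#' @param log_bf_E,log_bf_P,log_bf_EP Per-gene log Bayes factors for the
#'   expression-only, protein-only, and both-products models.
#' @param prior_value Per-gene composite prior `pi * f` in \[0, 1\].
#' @param h Simplex of conditional model proportions `(h_E, h_P, h_EP)`.
#' @return A tibble with columns `post_M0`, `post_ME`, `post_MP`,
#'   `post_MEP` (rows sum to 1).
#' @export
#' @examples
#' posterior_model_probs(0, 0, 0, prior_value = 0.5, h = rep(1 / 3, 3))
posterior_model_probs <- function(log_bf_E, log_bf_P, log_bf_EP,
                                  prior_value, h = rep(1 / 3, 3)) {
  h <- check_simplex(h, 3L)
  check_prob(prior_value, "prior_value")
  n <- max(length(log_bf_E), length(prior_value))
  lbf <- cbind(rep_len(log_bf_E, n), rep_len(log_bf_P, n),
               rep_len(log_bf_EP, n))
  pf <- rep_len(prior_value, n)
  lh <- ifelse(h > 0, log(h), -Inf)
  lpost <- cbind(ifelse(pf < 1, log1p(-pf), -Inf),
                 sweep(lbf, 2L, lh, "+") + ifelse(pf > 0, log(pf), -Inf))
  norm <- row_logsumexp(lpost)
  post <- exp(lpost - norm)
  tibble::tibble(post_M0 = post[, 1], post_ME = post[, 2],
                 post_MP = post[, 3], post_MEP = post[, 4])
}

#' Gene-product relevance probabilities
#'
#' Marginalizes posterior mechanism-model probabilities into per-product
#' relevance: the posterior probability that a product exerts an effect on
#' the trait is the sum of the posteriors of every model containing it
#' (`relevance_E = post_ME + post_MEP`; `relevance_P = post_MP + post_MEP`).
#'
#' @param mp A tibble with columns `post_ME`, `post_MP`, `post_MEP` (as from
#'   [posterior_model_probs()]).
#' @return `mp` with columns `relevance_E` and `relevance_P` added.
#' @export
relevance_probs <- function(mp) {
  stopifnot(all(c("post_ME", "post_MP", "post_MEP") %in% names(mp)))
  dplyr::mutate(mp,
                relevance_E = pmin(.data$post_ME + .data$post_MEP, 1),
                relevance_P = pmin(.data$post_MP + .data$post_MEP, 1))
}
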