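#' Shrinkage Bayes factor from a Wald statistic
#'
#' Converts a Wald statistic with `df` degrees of freedom into a log Bayes
#' factor against the null, averaging a conjugate shrinkage kernel over a
#' grid of prior-to-residual variance ratios `tau`:
#' `BF = mean_tau (1 + tau)^(-df / 2) * exp((W / 2) * tau / (1 + tau))`.
#' The value is strictly increasing in `W` for fixed `df` and reduces to the
#' standard z-score shrinkage Bayes factor at `df = 1`.
#'
#' @param W Non-negative Wald statistic(s).
#' @param df Degrees of freedom, 1 or 2 (scalar or vector aligned to `W`).
#' @param tau_grid Positive prior variance ratios averaged uniformly.
#' @return Log Bayes factor(s), same length as `W`.
#' @export
#' @examples
#' wald_to_log_bf(0, df = 1, tau_grid = 1)  # log(1/sqrt(2))
wald_to_log_bf <- function(W, df, tau_grid = c(1, 2, 4, 8, 16)) {
  if (length(tau_grid) == 0) abort_arg("`tau_grid` must be non-empty.")
  if (any(tau_grid <= 0)) abort_arg("`tau_grid` values must be positive.")
  if (any(W < 0)) abort_arg("`W` must be non-negative.")
  if (!all(df %in% c(1L, 2L))) abort_arg("`df` must be 1 or 2.")
  df <- rep_len(df, length(W))
  shrink <- tau_grid / (1 + tau_grid)
  # terms[i, j] = -df_i/2 * log(1 + tau_j) + (W_i / 2) * shrink_j
  terms <- outer(W / 2, shrink) - outer(df / 2, log1p(tau_grid))
  if (length(W) == 1L) {
    logmeanexp(drop(terms))
  } else {
    row_logsumexp(terms) - log(length(tau_grid))
  }
}

#' Model-specific Bayes factors from the bivariate instrument scores
#'
#' Computes log Bayes factors for the expression-only, protein-only, and
#' both-products mechanism models from the pair of instrument-level
#' association z-scores and the correlation `rho` between the two
#' instruments. The bivariate score is modelled as
#' `z ~ N(Lambda phi, Lambda)` with `Lambda = [[1, rho], [rho, 1]]` and a
#' `N(0, tau)` prior on each active coordinate of `phi`, averaged uniformly
#' over `tau_grid`. Modelling `Lambda` is what lets a single-product model
#' explain the correlation-induced signal leakage into the other product's
#' instrument rather than crediting it to the joint model. In addition,
#' single-product models carry a small fixed prior variance `leak` on the
#' inactive coordinate, absorbing the apparent cross-product association of
#' a few chi-square units generated by prediction-weight estimation error
#' (without it, genuinely single-product genes are systematically
#' attributed to the joint model). At `rho = 0` and `leak = 0` the
#' single-product Bayes factors reduce to the scalar 1-df shrinkage Bayes
#' factor [wald_to_log_bf()] and the joint Bayes factor factorizes into
#' their product.
#'
#' @param z_E,z_P Instrument-level association z-scores (vectors over
#'   genes).
#' @param rho Instrument correlation(s) in \[-1, 1\]; clamped to 0.999 in
#'   magnitude for stability.
#' @param tau_grid Positive prior variance ratios averaged uniformly. The
#'   default spans weak to very strong signals; the upper end sets the
#'   parsimony penalty that separates single-product from joint models.
#' @param leak Fixed cross-product prior variance for single-product
#'   models (default 2), on the squared-z-score scale; non-negative.
#' @return A tibble with columns `log_bf_E`, `log_bf_P`, `log_bf_EP`.
#' @export
model_log_bfs <- function(z_E, z_P, rho,
                          tau_grid = c(1, 2, 4, 8, 16, 32, 64, 128),
                          leak = 2) {
  if (length(tau_grid) == 0 || any(tau_grid <= 0)) {
    abort_arg("`tau_grid` must be non-empty and positive.")
  }
  if (length(leak) != 1 || leak < 0) {
    abort_arg("`leak` must be a single non-negative value.")
  }
  n <- max(length(z_E), length(z_P), length(rho))
  z_E <- rep_len(z_E, n); z_P <- rep_len(z_P, n)
  rho <- pmin(pmax(rep_len(rho, n), -0.999), 0.999)
  omr2 <- 1 - rho^2
  q_null <- (z_E^2 - 2 * rho * z_E * z_P + z_P^2) / omr2
  # Sigma_m = Lambda + Lambda S Lambda with S = diag(sa, sb)
  one_model <- function(sa, sb) {
    terms <- matrix(0, n, length(tau_grid))
    for (j in seq_along(tau_grid)) {
      ta <- sa[j]; tb <- sb[j]
      s11 <- 1 + ta + tb * rho^2
      s22 <- 1 + ta * rho^2 + tb
      s12 <- rho * (1 + ta + tb)
      dS <- s11 * s22 - s12^2
      q_m <- (s22 * z_E^2 - 2 * s12 * z_E * z_P + s11 * z_P^2) / dS
      terms[, j] <- 0.5 * (q_null - q_m) - 0.5 * log(dS / omr2)
    }
    row_logsumexp(terms) - log(length(tau_grid))
  }
  lk <- rep(leak, length(tau_grid))
  tibble::tibble(log_bf_E = one_model(tau_grid, lk),
                 log_bf_P = one_model(lk, tau_grid),
                 log_bf_EP = one_model(tau_grid, tau_grid))
}

#' Truncated colocalization prior function
#'
#' Combines per-product gene-level colocalization probabilities into the
#' prior evidence factor `f` of the putative-causality prior. The per-gene
#' colocalization summary `c` is `max(pE, pP)` (default; "at least one
#' product shows colocalization") or `1 - (1 - pE)(1 - pP)`. With the
#' `"linear"` shape, `f = c` if `c >= threshold` and 0 otherwise; with the
#' `"step"` shape, `f = 1{c >= threshold}`. Genes with zero colocalization
#' evidence on every product always receive `f = 0`: colocalization is a
#' necessary condition for putative causality.
#'
#' @param pE,pP Gene-level colocalization probabilities for the two
#'   products, in \[0, 1\] (vectors allowed).
#' @param shape `"linear"` (default) or `"step"`.
#' @param threshold Truncation threshold `t` (default 0.05).
#' @param combine `"max"` (default) or `"one_minus_prod"`.
#' @return `f` value(s) in \[0, 1\].
#' @export
prior_f <- function(pE, pP, shape = c("linear", "step"), threshold = 0.05,
                    combine = c("max", "one_minus_prod")) {
  shape <- match.arg(shape)
  combine <- match.arg(combine)
  check_prob(pE, "pE"); check_prob(pP, "pP")
  check_prob(threshold, "threshold")
  cc <- if (combine == "max") pmax(pE, pP) else 1 - (1 - pE) * (1 - pP)
  f <- switch(shape,
              linear = ifelse(cc >= threshold, cc, 0),
              step = as.numeric(cc >= threshold))
  ifelse(pE == 0 & pP == 0, 0, f)
}

#' Composite prior probability of putative causality
#'
#' The prior of the gene probability of putative causality:
#' `pi * f(pE, pP)` with the truncated prior function [prior_f()].
#'
#' @param pE,pP Gene-level colocalization probabilities.
#' @param pi Mixture proportion of putatively causal genes, in \[0, 1\].
#' @inheritParams prior_f
#' @return Prior probability value(s) `pi * f` in \[0, 1\].
#' @export
#' @examples
#' prior_value(0.6, 0.1, pi = 0.5)  # 0.5 * 0.6 = 0.30
prior_value <- function(pE, pP, pi, shape = c("linear", "step"),
                        threshold = 0.05,
                        combine = c("max", "one_minus_prod")) {
  check_prob(pi, "pi")
  pi * prior_f(pE, pP, shape = shape, threshold = threshold,
               combine = combine)
}

#' Estimate the causal mixture proportion pi by EM
#'
#' Maximum-likelihood estimate of `pi` in the two-group marginal likelihood
#' `L = prod_i [(1 - pi * f_i) + pi * f_i * BF_i]`, where `f_i` is the
#' gene's colocalization prior factor and `BF_i` its overall Bayes factor.
#' The EM alternates posterior non-null responsibilities with a one-
#' dimensional M-step; the observed log-likelihood is non-decreasing across
#' iterations and convergence is declared when `|delta pi| < tol`.
#'
#' @param log_bf_overall Per-gene overall log Bayes factors.
#' @param f_values Per-gene prior factors `f` in \[0, 1\].
#' @param init Starting value (default 0.5).
#' @param tol Convergence tolerance on `pi` (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return A list with `pi`, `n_iter`, `converged`, and `log_lik`. If every
#'   `f` is zero, `pi` is unidentifiable: returns 0 with a warning. If every
#'   Bayes factor is 1 the likelihood is flat: returns `init` with a
#'   warning.
#' @export
estimate_pi <- function(log_bf_overall, f_values, init = 0.5, tol = 1e-8,
                        max_iter = 1000L) {
  if (length(log_bf_overall) < 2) abort_arg("Need at least 2 genes.")
  if (length(f_values) != length(log_bf_overall)) {
    abort_alignment("`f_values` must align with `log_bf_overall`.")
  }
  check_prob(f_values, "f_values")
  if (all(f_values == 0)) {
    warn("All prior factors are zero: pi is unidentifiable; returning 0.")
    return(list(pi = 0, n_iter = 0L, converged = FALSE, log_lik = 0))
  }
  if (all(abs(log_bf_overall) < 1e-12)) {
    warn("All Bayes factors equal 1: flat likelihood; returning `init`.")
    return(list(pi = init, n_iter = 0L, converged = FALSE, log_lik = 0))
  }
  keep <- f_values > 0
  f <- f_values[keep]
  lbf <- log_bf_overall[keep]
  loglik <- function(pi) {
    # log[(1 - pi f) + pi f BF] per gene, stably and vectorized
    a <- log(pi) + log(f) + lbf
    b <- log1p(-pi * f)
    m <- pmax(a, b)
    sum(m + log(exp(a - m) + exp(b - m)))
  }
  pi <- init
  ll <- loglik(pi)
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    # E-step: posterior non-null responsibility per gene
    la <- log(pi) + log(f) + lbf
    lb <- log1p(-pi * f)
    q <- 1 / (1 + exp(lb - la))
    q[pi == 0] <- 0
    # M-step: maximize sum q*log(pi f) + (1-q)*log(1 - pi f) over pi
    mstep <- function(p) sum(q * (log(p) + log(f)) + (1 - q) * log1p(-p * f))
    opt <- optimize(mstep, interval = c(1e-12, 1 - 1e-12), maximum = TRUE,
                    tol = 1e-10)
    pi_new <- opt$maximum
    # snap to boundary if it improves the M-step objective
    ll_new <- loglik(pi_new)
    if (ll_new < ll - 1e-8) {
      warn("EM log-likelihood decreased; stopping early.")
      break
    }
    delta <- abs(pi_new - pi)
    pi <- pi_new
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  list(pi = min(max(pi, 0), 1), n_iter = n_iter, converged = converged,
       log_lik = ll)
}

#' Gene probability of putative causality
#'
#' Posterior probability that at least one gene product affects the trait,
#' by Bayes' rule from the composite prior and the overall Bayes factor:
#' `GPPC = prior * BF / (prior * BF + 1 - prior)`, computed stably in log
#' space. Its complement is a local false discovery rate.
#'
#' @param prior Composite prior probability(ies), `pi * f`.
#' @param log_bf_overall Overall log Bayes factor(s).
#' @return GPPC value(s) in \[0, 1\]; exactly 0 whenever `prior = 0`.
#' @export
#' @examples
#' compute_gppc(0.1, log(9))  # 0.5
compute_gppc <- function(prior, log_bf_overall) {
  check_prob(prior, "prior")
  posterior_from_log_bf(prior, log_bf_overall)
}

#' Bayesian false discovery rate control from local fdrs
#'
#' Sorts local false discovery rates in ascending order and rejects the
#' largest prefix whose running mean (the Bayesian FDR of the rejection
#' set) stays at or below `alpha`. Tied lfdr values at the rejection
#' boundary are included or excluded as a block.
#'
#' @param lfdrs Local false discovery rates in \[0, 1\].
#' @param alpha Target FDR level in (0, 1); default 0.05.
#' @return Logical rejection flags in the original order.
#' @export
#' @examples
#' bayesian_fdr_control(c(0.01, 0.04, 0.20), alpha = 0.05)
bayesian_fdr_control <- function(lfdrs, alpha = 0.05) {
  check_prob(lfdrs, "lfdrs")
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_arg("`alpha` must lie strictly in (0, 1).")
  }
  n <- length(lfdrs)
  if (n == 0) return(logical(0))
  ord <- order(lfdrs)
  sorted <- lfdrs[ord]
  cmeans <- cumsum(sorted) / seq_len(n)
  k <- max(c(0L, which(cmeans <= alpha)))
  if (k > 0 && k < n && sorted[k + 1] == sorted[k]) {
    # boundary cuts a tie block: all-or-none
    block <- which(sorted == sorted[k])
    k_full <- max(block)
    k <- if (cmeans[k_full] <= alpha) k_full else min(block) - 1L
  }
  flags <- logical(n)
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Per-gene Bayes factors for the three non-null mechanism models
#'
#' Maps joint and single-product Wald evidence into log Bayes factors for
#' the expression-only, protein-only, and both-products models, plus the
#' overall log Bayes factor used by the gene probability of putative
#' causality (a uniform or weighted mixture of the three).
#'
#' @param wald_tbl Tibble with one row per gene: `gene_id`, `z_E`, `z_P`,
#'   `rho` (for the default bivariate method), and `W_E`, `W_P`, `W_joint`,
#'   `df_joint` (for `method = "wald"`), as produced by tidying
#'   `wald_result`s.
#' @param tau_grid Prior variance-ratio grid; `NULL` (default) uses each
#'   method's own default (`c(1, 2, 4, 8, 16, 32, 64, 128)` for the
#'   bivariate model, `c(1, 2, 4, 8, 16)` for the scalar Wald conversion).
#' @param mixture Weights over (E, P, E+P) for the overall Bayes factor;
#'   default uniform.
#' @param method `"bivariate"` (default) computes the three model Bayes
#'   factors from the correlated instrument scores via [model_log_bfs()];
#'   `"wald"` converts each model's scalar Wald statistic independently via
#'   [wald_to_log_bf()].
#' @param leak Cross-product leak prior variance for the bivariate method;
#'   see [model_log_bfs()].
#' @return Tibble with columns `gene_id`, `log_bf_E`, `log_bf_P`,
#'   `log_bf_EP`, `log_bf_overall`.
#' @export
gene_bayes_factors <- function(wald_tbl, tau_grid = NULL,
                               mixture = c(1, 1, 1) / 3,
                               method = c("bivariate", "wald"),
                               leak = 2) {
  method <- match.arg(method)
  if (length(mixture) != 3 || any(mixture < 0) || sum(mixture) <= 0) {
    abort_arg("`mixture` must be 3 non-negative weights.")
  }
  mixture <- mixture / sum(mixture)
  if (is.null(tau_grid)) {
    tau_grid <- if (method == "bivariate") {
      c(1, 2, 4, 8, 16, 32, 64, 128)
    } else {
      c(1, 2, 4, 8, 16)
    }
  }
  if (method == "bivariate") {
    stopifnot(all(c("gene_id", "z_E", "z_P", "rho") %in% names(wald_tbl)))
    bfs <- model_log_bfs(wald_tbl$z_E, wald_tbl$z_P, wald_tbl$rho,
                         tau_grid, leak = leak)
    lbf_E <- bfs$log_bf_E; lbf_P <- bfs$log_bf_P; lbf_EP <- bfs$log_bf_EP
  } else {
    stopifnot(all(c("gene_id", "W_E", "W_P", "W_joint", "df_joint") %in%
                    names(wald_tbl)))
    lbf_E <- wald_to_log_bf(wald_tbl$W_E, 1L, tau_grid)
    lbf_P <- wald_to_log_bf(wald_tbl$W_P, 1L, tau_grid)
    lbf_EP <- wald_to_log_bf(wald_tbl$W_joint, wald_tbl$df_joint, tau_grid)
  }
  lmat <- cbind(lbf_E, lbf_P, lbf_EP)
  overall <- row_logsumexp(sweep(lmat, 2L, log(mixture), "+"))
  tibble::tibble(gene_id = wald_tbl$gene_id,
                 log_bf_E = lbf_E, log_bf_P = lbf_P, log_bf_EP = lbf_EP,
                 log_bf_overall = overall)
}
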