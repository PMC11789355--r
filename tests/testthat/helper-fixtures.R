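# Small in-code fixtures shared across test files.

toy_evidence <- function() {
  tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    product = c("E", "E", "P", "E", "P"),
    snp_id = c("rs1", "rs2", "rs2", "rs9", "rs9"),
    weight = c(0.5, -0.2, 0.9, 1.1, 0.3),
    coloc_prob = c(0.8, 0.8, 0.4, 0.05, 0.6))
}

# tiny multi-cohort dataset for pipeline-level tests
tiny_dataset <- function(n_genes = 30, seed = 7, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, n_per_cohort = 300,
                              snps_per_gene = 60, seed = seed, ...))
}

# synthetic per-gene Bayes-factor table drawn from the mixture model itself
synthetic_bf_table <- function(n = 400, h = c(0.5, 0.25, 0.25),
                               signal = 6, seed = 1) {
  set.seed(seed)
  mech <- sample(1:3, n, replace = TRUE, prob = h)
  lbf <- matrix(rnorm(n * 3, -1, 1), n, 3)
  for (i in seq_len(n)) lbf[i, mech[i]] <- rnorm(1, signal, 2)
  colnames(lbf) <- c("E", "P", "EP")
  list(lbf = lbf, mech = mech)
}

# independent oracle: h log-likelihood evaluated directly (no EM machinery)
h_loglik_direct <- function(h, lbf, prior_values) {
  keep <- prior_values > 0
  lbf <- lbf[keep, , drop = FALSE]
  pf <- prior_values[keep]
  lt <- sweep(lbf, 2, log(pmax(h, 1e-300)), "+")
  m <- apply(lt, 1, max)
  lmix <- m + log(rowSums(exp(lt - m)))
  sum(log((1 - pf) + pf * exp(lmix)))
}

# independent oracle: grid search over the 2-simplex (step 0.01)
h_grid_search <- function(lbf, prior_values, step = 0.01) {
  best <- NULL
  best_ll <- -Inf
  for (a in seq(step, 1 - 2 * step, step)) {
    for (b in seq(step, 1 - a - step, step)) {
      h <- c(a, b, 1 - a - b)
      ll <- h_loglik_direct(h, lbf, prior_values)
      if (ll > best_ll) {
        best_ll <- ll
        best <- h
      }
    }
  }
  best
}

# independent oracle: single-causal fine-mapping by explicit enumeration of
# the k+1 causal configurations in plain arithmetic
finemap_enumerate <- function(log_abf, prior_per_snp) {
  bf <- exp(log_abf)
  k <- length(bf)
  null_w <- 1 - k * prior_per_snp
  weights <- c(prior_per_snp * bf, null_w)
  weights / sum(weights)
}
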