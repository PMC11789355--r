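#' Per-SNP marginal association scan
#'
#' Simple regression of a centered trait on each centered genotype column
#' (no intercept), returning effect estimates, standard errors, and z-scores.
#' This is the workhorse that produces molecular-QTL and GWAS single-SNP
#' statistics from individual-level data.
#'
#' @param G Genotype matrix (individuals x SNPs); columns are centered
#'   internally.
#' @param y Trait vector; centered internally.
#' @return A tibble with columns `snp_id`, `effect`, `se`, `z`. Monomorphic
#'   SNPs get effect 0, infinite `se`, and `z = 0`.
#' @export
marginal_scan <- function(G, y) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (n != length(y)) abort_alignment("nrow(G) must equal length(y).")
  if (n < 3) abort_arg("Need at least 3 individuals for a marginal scan.")
  Gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ss <- colSums(Gc^2)
  xy <- drop(crossprod(Gc, yc))
  yy <- sum(yc^2)
  ok <- ss > 0
  effect <- ifelse(ok, xy / ss, 0)
  rss <- pmax(yy - effect^2 * ss, 0)
  se <- ifelse(ok, sqrt(rss / ((n - 2) * ss)), Inf)
  z <- ifelse(ok & se > 0, effect / se, 0)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  tibble::tibble(snp_id = ids, effect = effect, se = se, z = z)
}

#' Build an instrument weight vector for one gene product
#'
#' Converts per-SNP association evidence into prediction weights for the
#' genetically predicted gene product. Two built-in methods:
#' * `"top_snp"`: a single weight, the effect estimate at the SNP with the
#'   largest `|z|` (ties broken by lexicographically smaller `snp_id`) —
#'   the strongest-QTL predictor commonly used for protein abundance;
#' * `"pip_weighted"`: `weight_j = pip_j * effect_j`, mirroring weights built
#'   from probabilistic fine-mapping results (requires `pip`).
#'
#' @param assoc Tibble with columns `snp_id`, `effect`, `se` (as from
#'   [marginal_scan()]).
#' @param method `"top_snp"` or `"pip_weighted"`.
#' @param pip For `method = "pip_weighted"`: per-SNP posterior inclusion
#'   probabilities aligned to `assoc` rows, e.g. from
#'   [finemap_single_causal()].
#' @param product Label attached to the weights (e.g. `"E"` or `"P"`).
#' @return A tibble of class `weight_vector` with columns `snp_id`, `weight`
#'   and attributes `product` and `method`; at least one entry is nonzero.
#' @export
build_weights <- function(assoc, method = c("top_snp", "pip_weighted"),
                          pip = NULL, product = NA_character_) {
  method <- match.arg(method)
  if (nrow(assoc) < 1) abort_arg("`assoc` must contain at least one SNP.")
  ok <- is.finite(assoc$effect) & is.finite(assoc$se)
  if (!any(ok)) abort_arg("No SNP with finite effect and standard error.")
  assoc <- assoc[ok, , drop = FALSE]
  if (method == "top_snp") {
    absz <- abs(assoc$effect / assoc$se)
    top <- which(absz == max(absz))
    if (length(top) > 1) {
      top <- top[order(assoc$snp_id[top])][1L]
    }
    out <- tibble::tibble(snp_id = assoc$snp_id[top],
                          weight = assoc$effect[top])
  } else {
    if (is.null(pip) || length(pip) != nrow(assoc)) {
      abort_arg("`pip` must align with `assoc` for method = 'pip_weighted'.")
    }
    out <- tibble::tibble(snp_id = assoc$snp_id,
                          weight = pip * assoc$effect)
  }
  if (all(out$weight == 0)) {
    abort(
      "Degenerate weights: all entries are zero.",
      class = "multipcg_degenerate_weight_error")
  }
  structure(out, product = product, method = method,
            class = c("weight_vector", class(out)))
}

#' Genetically predicted gene product
#'
#' Computes `G %*% w` after centering the genotype columns, yielding a
#' centered prediction of the molecular phenotype from its instrument
#' weights.
#'
#' @param G Genotype matrix with column names covering the weight SNPs.
#' @param w Weight tibble (`snp_id`, `weight`), e.g. from [build_weights()].
#' @return A centered numeric vector of length `nrow(G)`.
#' @export
predict_product <- function(G, w) {
  G <- as.matrix(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  missing <- setdiff(w$snp_id, ids)
  if (length(missing) > 0) {
    abort_alignment(sprintf("Weight SNP(s) absent from genotypes: %s",
                            paste(missing, collapse = ", ")))
  }
  cols <- match(w$snp_id, ids)
  Gc <- scale(G[, cols, drop = FALSE], center = TRUE, scale = FALSE)
  drop(Gc %*% w$weight)
}

#' Multi-SNP instrument weights by forward conditional selection
#'
#' Builds a multi-signal prediction model for a molecular trait by forward
#' stepwise selection of SNPs (the conditional-analysis construction used
#' throughout the QTL literature): at each step the SNP with the largest
#' conditional association, given the SNPs already selected, enters the
#' model if its conditional `|z|` exceeds `z_threshold`; the final weights
#' are the joint least-squares effects of the selected SNPs. This captures
#' allelic heterogeneity (several causal QTL signals per gene) that
#' single-SNP weights miss. If no SNP passes the threshold, the strongest
#' marginal SNP is used alone (top-SNP fallback).
#'
#' @param G Genotype matrix (individuals x SNPs, with column names).
#' @param y Molecular trait vector.
#' @param max_snps Maximum number of selected SNPs (default 5).
#' @param z_threshold Conditional |z| required for entry (default 3.9,
#'   roughly p < 1e-4).
#' @param product Label attached to the weights.
#' @return A `weight_vector` tibble (`snp_id`, `weight`) with
#'   `method = "conditional"`.
#' @export
conditional_weights <- function(G, y, max_snps = 5L, z_threshold = 3.9,
                                product = NA_character_, snps = NULL) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (n != length(y)) abort_alignment("nrow(G) must equal length(y).")
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  selected_ids <- if (is.null(snps)) {
    conditional_select(G, y, max_snps, z_threshold)
  } else {
    missing <- setdiff(snps, ids)
    if (length(missing) > 0) {
      abort_alignment(sprintf("SNP(s) absent from genotypes: %s",
                              paste(missing, collapse = ", ")))
    }
    snps
  }
  if (length(selected_ids) == 0) {
    return(build_weights(marginal_scan(G, y), method = "top_snp",
                         product = product))
  }
  Gc <- scale(G, center = TRUE, scale = FALSE)
  X <- Gc[, match(selected_ids, ids), drop = FALSE]
  beta <- drop(stats::lm.fit(X, y - mean(y))$coefficients)
  beta[is.na(beta)] <- 0
  out <- tibble::tibble(snp_id = selected_ids, weight = unname(beta))
  if (all(out$weight == 0)) {
    return(build_weights(marginal_scan(G, y), method = "top_snp",
                         product = product))
  }
  structure(out, product = product, method = "conditional",
            class = c("weight_vector", class(out)))
}

#' @describeIn conditional_weights Forward stepwise SNP selection only:
#'   returns the selected SNP ids (possibly none).
#' @export
conditional_select <- function(G, y, max_snps = 5L, z_threshold = 3.9) {
  G <- as.matrix(G)
  n <- nrow(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  Xr <- scale(G, center = TRUE, scale = FALSE)
  yr <- y - mean(y)
  selected <- integer(0)
  for (step in seq_len(max_snps)) {
    ss <- colSums(Xr^2)
    ok <- ss > 1e-10
    if (!any(ok)) break
    b <- ifelse(ok, drop(crossprod(Xr, yr)) / ss, 0)
    rss <- pmax(sum(yr^2) - b^2 * ss, 0)
    dfres <- max(n - 1 - length(selected), 1)
    se <- ifelse(ok, sqrt(rss / (dfres * ss)), Inf)
    z <- ifelse(ok & se > 0, abs(b) / se, 0)
    z[selected] <- 0
    j <- which(z == max(z))
    if (length(j) > 1) j <- j[order(ids[j])][1L]
    if (z[j] < z_threshold) break
    xj <- Xr[, j]
    proj <- drop(crossprod(Xr, xj)) / sum(xj^2)
    Xr <- Xr - outer(xj, proj)
    yr <- yr - xj * (sum(xj * yr) / sum(xj^2))
    selected <- c(selected, j)
  }
  ids[selected]
}

#' Rescale allelic-scale weights to the standardized-genotype scale
#'
#' The summary-statistics association test operates on z-scores, which live
#' on the standardized-genotype scale. Weights estimated on the allelic
#' (dosage) scale are mapped onto that scale by multiplying each weight by
#' the genotype standard deviation of its SNP.
#'
#' @param w Weight tibble (`snp_id`, `weight`).
#' @param G Reference genotype matrix supplying per-SNP standard deviations.
#' @return A weight tibble on the standardized scale.
#' @export
standardize_weights <- function(w, G) {
  G <- as.matrix(G)
  ids <- colnames(G)
  missing <- setdiff(w$snp_id, ids)
  if (length(missing) > 0) {
    abort_alignment(sprintf("Weight SNP(s) absent from genotypes: %s",
                            paste(missing, collapse = ", ")))
  }
  sds <- apply(G[, match(w$snp_id, ids), drop = FALSE], 2L, sd)
  dplyr::mutate(w, weight = .data$weight * sds)
}

new_wald_result <- function(r2_joint, W_joint, df_joint, W_E, W_P,
                            z_E, z_P, n, rank_deficient, rho) {
  structure(list(r2_joint = r2_joint, W_joint = W_joint,
                 df_joint = as.integer(df_joint),
                 W_E = W_E, W_P = W_P, z_E = z_E, z_P = z_P,
                 n = n, rank_deficient = rank_deficient, rho = rho),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf(
    "<wald_result> W_joint = %.3f (df %d), R2 = %.4f, z_E = %.2f, z_P = %.2f%s\n",
    x$W_joint, x$df_joint, x$r2_joint, x$z_E, x$z_P,
    if (x$rank_deficient) " [rank deficient]" else ""))
  invisible(x)
}

#' @describeIn joint_wald_individual Tidy a `wald_result` into a one-row
#'   tibble.
#' @param x A `wald_result`.
#' @param ... Unused.
#' @method tidy wald_result
#' @export
tidy.wald_result <- function(x, ...) {
  tibble::tibble(r2_joint = x$r2_joint, W_joint = x$W_joint,
                 df_joint = x$df_joint, W_E = x$W_E, W_P = x$W_P,
                 z_E = x$z_E, z_P = x$z_P, rho = x$rho, n = x$n,
                 rank_deficient = x$rank_deficient)
}

single_fit_z <- function(x, y, n) {
  sxx <- sum(x^2)
  if (sxx <= 0) return(list(z = 0, W = 0, r2 = 0))
  b <- sum(x * y) / sxx
  yy <- sum(y^2)
  rss <- max(yy - b^2 * sxx, 0)
  r2 <- if (yy > 0) 1 - rss / yy else 0
  se <- sqrt(rss / ((n - 1) * sxx))
  z <- if (se > 0) b / se else sign(b) * sqrt(.Machine$double.xmax)
  list(z = z, W = z^2, r2 = r2)
}

#' Joint association test of a trait on two predicted gene products
#'
#' Fits the no-intercept least-squares regression of the (centered) trait on
#' the two (centered) predicted gene products and summarizes the joint and
#' per-product evidence. The joint R-squared equals the squared canonical
#' correlation between the trait and the pair of predictions; the joint Wald
#' statistic is `n * R2 / (1 - R2)` with 2 degrees of freedom (1 if the two
#' predictions are collinear, in which case the stronger product is kept and
#' `rank_deficient` is set).
#'
#' @param Y Centered trait vector.
#' @param Ehat,Phat Centered predicted gene products (see
#'   [predict_product()]); not both constant.
#' @param collinear_tol Absolute correlation between `Ehat` and `Phat` above
#'   which the design is treated as rank 1.
#' @return A `wald_result` with elements `r2_joint`, `W_joint`, `df_joint`,
#'   `W_E`, `W_P`, `z_E`, `z_P` (single-regressor statistics), `n`, and
#'   `rank_deficient`.
#' @export
joint_wald_individual <- function(Y, Ehat, Phat, collinear_tol = 0.999) {
  n <- length(Y)
  if (length(Ehat) != n || length(Phat) != n) {
    abort_alignment("`Y`, `Ehat`, `Phat` must have equal length.")
  }
  if (n < 10) abort_arg("Need at least 10 observations.")
  Y <- Y - mean(Y)
  Ehat <- Ehat - mean(Ehat)
  Phat <- Phat - mean(Phat)
  yy <- sum(Y^2)
  if (yy <= 0) {
    abort("Constant `Y`: joint statistic undefined.",
          class = "multipcg_undefined_statistic_error")
  }
  se_const <- sum(Ehat^2) <= 0
  sp_const <- sum(Phat^2) <= 0
  if (se_const && sp_const) {
    abort_arg("`Ehat` and `Phat` must not both be constant.")
  }
  fe <- single_fit_z(Ehat, Y, n)
  fp <- single_fit_z(Phat, Y, n)
  rho <- if (se_const || sp_const) 1 else cor(Ehat, Phat)
  rank_deficient <- se_const || sp_const || abs(rho) > collinear_tol
  if (rank_deficient) {
    keep <- if (fe$W >= fp$W) fe else fp
    r2 <- keep$r2
    W <- n * r2 / max(1 - r2, .Machine$double.eps)
    return(new_wald_result(r2, W, 1L, fe$W, fp$W, fe$z, fp$z, n, TRUE,
                           sign(rho)))
  }
  X <- cbind(Ehat, Phat)
  fit <- stats::lm.fit(X, Y)
  rss <- sum(fit$residuals^2)
  r2 <- max(0, min(1 - rss / yy, 1 - 1e-12))
  W <- n * r2 / (1 - r2)
  new_wald_result(r2, W, 2L, fe$W, fp$W, fe$z, fp$z, n, FALSE, rho)
}

#' Joint association test from GWAS summary statistics
#'
#' Summary-statistics approximation of [joint_wald_individual()]: with
#' per-SNP z-scores `z`, LD matrix `R`, and instrument weight vectors `wE`,
#' `wP` (on the same standardized scale as `z`; see
#' [standardize_weights()]), the instrument-level scores are
#' `u = (wE'z, wP'z)` with covariance
#' `Sigma = [[wE'R wE, wE'R wP], [., wP'R wP]]`, and the joint Wald
#' statistic is the quadratic form `u' Sigma^{-1} u` on 2 degrees of
#' freedom. A small ridge (`1e-8 * trace`) stabilizes near-singular
#' `Sigma`; if the two instruments are nearly collinear
#' (`|rho| > collinear_tol`) the statistic drops to 1 degree of freedom
#' using the stronger product.
#'
#' @param gs A [gwas_summary()] object.
#' @param wE,wP Weight tibbles (`snp_id`, `weight`); SNPs must be present in
#'   `gs`.
#' @param collinear_tol Instrument correlation above which the design is
#'   treated as rank 1.
#' @return A `wald_result` (with `r2_joint = W_joint / (n + W_joint)`, the
#'   implied squared canonical correlation).
#' @export
joint_wald_summary <- function(gs, wE, wP, collinear_tol = 0.999) {
  stopifnot(inherits(gs, "gwas_summary"))
  expand <- function(w) {
    missing <- setdiff(w$snp_id, gs$snp_ids)
    if (length(missing) > 0) {
      abort_alignment(sprintf("Weight SNP(s) absent from summary data: %s",
                              paste(missing, collapse = ", ")))
    }
    v <- numeric(length(gs$snp_ids))
    v[match(w$snp_id, gs$snp_ids)] <- w$weight
    v
  }
  vE <- expand(wE)
  vP <- expand(wP)
  R <- gs$ld
  s11 <- drop(crossprod(vE, R %*% vE))
  s22 <- drop(crossprod(vP, R %*% vP))
  s12 <- drop(crossprod(vE, R %*% vP))
  if (s11 <= 0 || s22 <= 0) {
    abort("Non-positive instrument variance w'Rw: invalid LD or weights.",
          class = "multipcg_invalid_ld_error")
  }
  u1 <- sum(vE * gs$z)
  u2 <- sum(vP * gs$z)
  z_E <- u1 / sqrt(s11)
  z_P <- u2 / sqrt(s22)
  W_E <- z_E^2
  W_P <- z_P^2
  rho <- s12 / sqrt(s11 * s22)
  if (abs(rho) > collinear_tol) {
    W <- max(W_E, W_P)
    r2 <- W / (gs$n + W)
    return(new_wald_result(r2, W, 1L, W_E, W_P, z_E, z_P, gs$n, TRUE,
                           sign(rho)))
  }
  Sigma <- matrix(c(s11, s12, s12, s22), 2L, 2L)
  Sigma <- Sigma + diag(1e-8 * (s11 + s22), 2L)
  u <- c(u1, u2)
  W <- drop(crossprod(u, solve(Sigma, u)))
  r2 <- W / (gs$n + W)
  new_wald_result(r2, W, 2L, W_E, W_P, z_E, z_P, gs$n, FALSE, rho)
}
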