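#' Run the end-to-end benchmark on simulated datasets
#'
#' For each dataset: extracts per-gene evidence ([analyze_dataset()]), fits
#' the multi-product empirical-Bayes model ([pcg_fit()]) and the two
#' single-product comparators ([single_product_fit()]), and scores realized
#' power and false discovery rate against the ground-truth mechanism
#' labels at the configured Bayesian FDR level. Also collects the EM
#' estimates of the mechanism proportions, the mean posterior model
#' probabilities stratified by true mechanism, and cumulative true- vs
#' false-discovery curves from the gene-product relevance scores.
#'
#' @param datasets A `sim_dataset` or [sim_config()], or a list of either.
#'   Configs are simulated one at a time and discarded after scoring, so a
#'   many-dataset benchmark holds only one dataset in memory.
#' @param alpha Target Bayesian FDR level (default 0.05).
#' @param mode,weight_method Passed to [analyze_dataset()].
#' @param ... Further arguments passed to [pcg_fit()].
#' @return An object of class `benchmark_report` with elements
#'   * `summary`: per-dataset power/FDR/rejections for each method,
#'   * `overall`: method-level means with Monte-Carlo standard errors,
#'   * `h_estimates`: EM mechanism-proportion estimates vs truth,
#'   * `strata`: mean posterior model probabilities by true mechanism,
#'   * `curves`: cumulative true/false discovery counts by relevance and
#'     single-product scores,
#'   * `product_discoveries`: per-product true/false discoveries at the
#'     FDR target for relevance-based and single-product rankings.
#' @export
run_benchmark <- function(datasets, alpha = 0.05,
                          mode = c("individual", "summary"),
                          weight_method = c("conditional", "pip_weighted",
                                            "top_snp"),
                          ...) {
  mode <- match.arg(mode)
  weight_method <- match.arg(weight_method)
  if (inherits(datasets, c("sim_dataset", "sim_config"))) {
    datasets <- list(datasets)
  }
  res <- purrr::imap(datasets, function(ds, i) {
    if (inherits(ds, "sim_config")) ds <- simulate_dataset(ds)
    out <- benchmark_one(ds, i, alpha, mode, weight_method, ...)
    rm(ds)
    out
  })
  summary_tbl <- dplyr::bind_rows(purrr::map(res, "summary"))
  overall <- summary_tbl |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      power_se = stats::sd(.data$power, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$power))),
      fdr_se = stats::sd(.data$fdr) / sqrt(dplyr::n()),
      power = mean(.data$power, na.rm = TRUE),
      fdr = mean(.data$fdr),
      n_datasets = dplyr::n(), .groups = "drop") |>
    dplyr::select("method", "power", "power_se", "fdr", "fdr_se",
                  "n_datasets")
  structure(list(
    summary = summary_tbl,
    overall = overall,
    h_estimates = dplyr::bind_rows(purrr::map(res, "h_estimates")),
    strata = dplyr::bind_rows(purrr::map(res, "strata")),
    curves = dplyr::bind_rows(purrr::map(res, "curves")),
    product_discoveries = dplyr::bind_rows(
      purrr::map(res, "product_discoveries")),
    alpha = alpha, mode = mode, weight_method = weight_method),
    class = "benchmark_report")
}

benchmark_one <- function(ds, dataset_id, alpha, mode, weight_method, ...) {
  tbl <- analyze_dataset(ds, mode = mode, weight_method = weight_method)
  truth <- dplyr::arrange(ds$truth, .data$gene_id)
  fit <- withCallingHandlers(
    pcg_fit(tbl, alpha = alpha, ...),
    warning = function(w) invokeRestart("muffleWarning"))
  fitE <- single_product_fit(tbl, "E", alpha = alpha)
  fitP <- single_product_fit(tbl, "P", alpha = alpha)

  genes <- dplyr::left_join(fit$genes, truth, by = "gene_id")
  is_pcg <- genes$mechanism != "M0"

  score_method <- function(reject, label) {
    tp <- sum(reject & is_pcg)
    fp <- sum(reject & !is_pcg)
    tibble::tibble(
      dataset = dataset_id, method = label,
      n_reject = sum(reject),
      power = if (sum(is_pcg) > 0) tp / sum(is_pcg) else NA_real_,
      fdr = if (sum(reject) > 0) fp / sum(reject) else 0)
  }
  summary_tbl <- dplyr::bind_rows(
    score_method(genes$fdr_reject, "multi"),
    score_method(fitE$genes$fdr_reject[match(genes$gene_id,
                                             fitE$genes$gene_id)],
                 "single_E"),
    score_method(fitP$genes$fdr_reject[match(genes$gene_id,
                                             fitP$genes$gene_id)],
                 "single_P"))

  mp <- ds$config$mech_probs
  h_true <- if (sum(mp[-1]) > 0) mp[-1] / sum(mp[-1]) else rep(NA_real_, 3)
  h_estimates <- tibble::tibble(
    dataset = dataset_id, component = c("E", "P", "EP"),
    estimate = unname(fit$h[c("E", "P", "EP")]), truth = h_true)

  strata <- genes |>
    dplyr::filter(.data$mechanism != "M0") |>
    dplyr::group_by(mechanism = .data$mechanism) |>
    dplyr::summarise(mean_post_ME = mean(.data$post_ME),
                     mean_post_MP = mean(.data$post_MP),
                     mean_post_MEP = mean(.data$post_MEP),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(dataset = dataset_id)

  curves <- dplyr::bind_rows(
    discovery_curve(genes$relevance_E, genes$mechanism %in% c("ME", "MEP"),
                    dataset_id, "relevance_E"),
    discovery_curve(genes$relevance_P, genes$mechanism %in% c("MP", "MEP"),
                    dataset_id, "relevance_P"),
    discovery_curve(abs(genes$z_E), genes$mechanism %in% c("ME", "MEP"),
                    dataset_id, "twas_E"),
    discovery_curve(abs(genes$z_P), genes$mechanism %in% c("MP", "MEP"),
                    dataset_id, "twas_P"),
    discovery_curve(genes$coloc_E, genes$mechanism %in% c("ME", "MEP"),
                    dataset_id, "coloc_E"),
    discovery_curve(genes$coloc_P, genes$mechanism %in% c("MP", "MEP"),
                    dataset_id, "coloc_P"),
    discovery_curve(fitE$genes$gppc[match(genes$gene_id,
                                          fitE$genes$gene_id)],
                    genes$mechanism %in% c("ME", "MEP"),
                    dataset_id, "single_E"),
    discovery_curve(fitP$genes$gppc[match(genes$gene_id,
                                          fitP$genes$gene_id)],
                    genes$mechanism %in% c("MP", "MEP"),
                    dataset_id, "single_P"))

  prod_disc <- dplyr::bind_rows(
    product_discoveries(genes$relevance_E,
                        genes$mechanism %in% c("ME", "MEP"), alpha,
                        dataset_id, "relevance_E"),
    product_discoveries(genes$relevance_P,
                        genes$mechanism %in% c("MP", "MEP"), alpha,
                        dataset_id, "relevance_P"),
    product_discoveries(fitE$genes$gppc[match(genes$gene_id,
                                              fitE$genes$gene_id)],
                        genes$mechanism %in% c("ME", "MEP"), alpha,
                        dataset_id, "single_E"),
    product_discoveries(fitP$genes$gppc[match(genes$gene_id,
                                              fitP$genes$gene_id)],
                        genes$mechanism %in% c("MP", "MEP"), alpha,
                        dataset_id, "single_P"))

  list(summary = summary_tbl, h_estimates = h_estimates, strata = strata,
       curves = curves, product_discoveries = prod_disc)
}

discovery_curve <- function(score, is_true, dataset_id, label) {
  ord <- order(score, decreasing = TRUE)
  tibble::tibble(
    dataset = dataset_id, score = label, rank = seq_along(ord),
    true_discoveries = cumsum(is_true[ord]),
    false_discoveries = cumsum(!is_true[ord]))
}

product_discoveries <- function(score, is_true, alpha, dataset_id, label) {
  reject <- bayesian_fdr_control(pmin(pmax(1 - score, 0), 1), alpha)
  tibble::tibble(dataset = dataset_id, score = label,
                 n_reject = sum(reject),
                 true_discoveries = sum(reject & is_true),
                 false_discoveries = sum(reject & !is_true))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d dataset(s), FDR target %.0f%%\n",
              max(x$summary$dataset), 100 * x$alpha))
  print(as.data.frame(x$overall), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @describeIn run_benchmark Per-dataset power/FDR rows as a tibble.
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) {
  x$summary
}

#' @describeIn run_benchmark Method-level means with Monte-Carlo standard
#'   errors.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  x$overall
}
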