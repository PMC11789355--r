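#' Plot a putative-causal-gene fit
#'
#' Scatter of gene-product relevance probabilities colored by rejection
#' status, the standard at-a-glance view of which product drives each
#' implicated gene.
#'
#' @param object A [pcg_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcg_fit
#' @export
autoplot.pcg_fit <- function(object, ...) {
  ggplot2::ggplot(object$genes,
                  ggplot2::aes(x = .data$relevance_E, y = .data$relevance_P,
                               colour = .data$fdr_reject)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = sprintf("FDR %.0f%% reject", 100 * object$alpha)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Relevance probability (expression)",
                  y = "Relevance probability (protein)") +
    ggplot2::theme_minimal()
}

#' Plot benchmark power and realized FDR by method
#'
#' @param object A `benchmark_report` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object: power and realized FDR per method with
#'   Monte-Carlo standard-error bars and the FDR target line.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  long <- object$overall |>
    tidyr::pivot_longer(c("power", "fdr"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(se = ifelse(.data$metric == "power", .data$power_se,
                              .data$fdr_se),
                  metric = factor(.data$metric, c("power", "fdr"),
                                  c("Power", "Realized FDR")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se), width = 0.2) +
    ggplot2::geom_hline(
      data = data.frame(metric = factor("Realized FDR",
                                        c("Power", "Realized FDR")),
                        y = object$alpha),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative true- vs false-discovery curves
#'
#' Ranks genes by each classification score and plots cumulative true
#' discoveries against false discoveries, aggregated across benchmark
#' datasets — the standard comparison of relevance-probability rankings to
#' single-product rankings.
#'
#' @param report A `benchmark_report`.
#' @param product `"E"` or `"P"`: which gene-product effect to score.
#' @return A ggplot object.
#' @export
plot_discovery_curves <- function(report, product = c("E", "P")) {
  product <- match.arg(product)
  scores <- c(paste0("relevance_", product), paste0("single_", product))
  agg <- report$curves |>
    dplyr::filter(.data$score %in% scores) |>
    dplyr::group_by(.data$score, .data$rank) |>
    dplyr::summarise(true_discoveries = mean(.data$true_discoveries),
                     false_discoveries = mean(.data$false_discoveries),
                     .groups = "drop")
  ggplot2::ggplot(agg,
                  ggplot2::aes(x = .data$false_discoveries,
                               y = .data$true_discoveries,
                               colour = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "False discoveries (mean per dataset)",
                  y = "True discoveries (mean per dataset)",
                  colour = "Score") +
    ggplot2::theme_minimal()
}
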