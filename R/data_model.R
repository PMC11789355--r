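#' Read per-gene molecular evidence from a delimited file
#'
#' The interchange format for gene evidence is a tab-separated table with a
#' header row and columns `gene_id`, `product`, `snp_id`, `weight`, and
#' `coloc_prob`. Each row gives the instrument weight of one SNP for one gene
#' product; `coloc_prob` is the gene-level colocalization probability of that
#' gene x product pair and must be constant within it. Weight vectors house
#' the per-product prediction weights used to form genetically predicted gene
#' products; colocalization probabilities feed the putative-causality prior.
#'
#' @param path Path to a tab-separated file.
#' @param require_all_products If `TRUE` (default), genes lacking one of the
#'   products observed in the file are dropped with a message: the joint
#'   analysis is defined for genes observed on every product. Set to `FALSE`
#'   to keep single-product genes (single-product fallback).
#'
#' @return A tibble with columns `gene_id`, `product`, `snp_id`, `weight`,
#'   `coloc_prob`, ordered by `gene_id`, validated. One gene x product block
#'   is one instrument weight vector.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' ev <- tibble::tibble(
#'   gene_id = c("g1", "g1", "g2", "g2"),
#'   product = c("E", "P", "E", "P"),
#'   snp_id = c("rs1", "rs2", "rs3", "rs3"),
#'   weight = c(0.5, -0.2, 1.0, 0.3),
#'   coloc_prob = c(0.9, 0.4, 0.1, 0.2)
#' )
#' write_gene_evidence(ev, tf)
#' read_gene_evidence(tf)
read_gene_evidence <- function(path, require_all_products = TRUE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_id", "product", "snp_id", "weight", "coloc_prob")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort_format(sprintf("Evidence file is missing required column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  tbl <- dplyr::mutate(tbl,
                       gene_id = as.character(.data$gene_id),
                       product = as.character(.data$product),
                       snp_id = as.character(.data$snp_id))
  validate_gene_evidence(tbl)
  if (require_all_products) {
    products <- sort(unique(tbl$product))
    keep <- tbl |>
      dplyr::distinct(.data$gene_id, .data$product) |>
      dplyr::count(.data$gene_id) |>
      dplyr::filter(.data$n == length(products)) |>
      dplyr::pull("gene_id")
    dropped <- setdiff(unique(tbl$gene_id), keep)
    if (length(dropped) > 0) {
      message(sprintf(
        "Dropping %d gene(s) without evidence for every product (%s): %s",
        length(dropped), paste(products, collapse = ", "),
        paste(head(dropped, 5L), collapse = ", ")))
      tbl <- dplyr::filter(tbl, .data$gene_id %in% keep)
    }
  }
  dplyr::arrange(tbl, .data$gene_id, .data$product, .data$snp_id)
}

#' Validate a gene-evidence table
#'
#' Checks the invariants of the evidence format: colocalization probabilities
#' in \[0, 1\] and constant within gene x product, non-empty weight vectors,
#' and SNP ids unique within each gene x product block. All violations are
#' aggregated and reported together with the offending genes and (1-based
#' data) line numbers.
#'
#' @param tbl A tibble as returned by [read_gene_evidence()].
#' @return `tbl`, invisibly, if valid; otherwise a validation error.
#' @export
validate_gene_evidence <- function(tbl) {
  problems <- character()
  bad_prob <- which(!is.finite(tbl$coloc_prob) |
                      tbl$coloc_prob < 0 | tbl$coloc_prob > 1)
  if (length(bad_prob) > 0) {
    genes <- unique(tbl$gene_id[bad_prob])
    problems <- c(problems, sprintf(
      "coloc_prob outside [0, 1] for gene(s) %s (line(s) %s)",
      paste(genes, collapse = ", "),
      paste(head(bad_prob, 10L), collapse = ", ")))
  }
  bad_weight <- which(!is.finite(tbl$weight))
  if (length(bad_weight) > 0) {
    problems <- c(problems, sprintf(
      "non-finite weight on line(s) %s",
      paste(head(bad_weight, 10L), collapse = ", ")))
  }
  by_gp <- dplyr::group_by(tbl, .data$gene_id, .data$product)
  const <- dplyr::summarise(by_gp,
                            n_coloc = dplyr::n_distinct(.data$coloc_prob),
                            n_snp = dplyr::n(),
                            n_unique = dplyr::n_distinct(.data$snp_id),
                            .groups = "drop")
  nc <- dplyr::filter(const, .data$n_coloc > 1)
  if (nrow(nc) > 0) {
    problems <- c(problems, sprintf(
      "coloc_prob not constant within gene x product for: %s",
      paste(sprintf("%s/%s", nc$gene_id, nc$product), collapse = ", ")))
  }
  dup <- dplyr::filter(const, .data$n_unique < .data$n_snp)
  if (nrow(dup) > 0) {
    problems <- c(problems, sprintf(
      "duplicated snp_id within gene x product for: %s",
      paste(sprintf("%s/%s", dup$gene_id, dup$product), collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort_validation(paste(c("Invalid gene evidence:", problems),
                           collapse = "\n- "))
  }
  invisible(tbl)
}

#' Write a gene-evidence table
#'
#' @param tbl Evidence tibble (see [read_gene_evidence()] for the format).
#' @param path Output path; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_gene_evidence <- function(tbl, path) {
  validate_gene_evidence(tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Construct a GWAS summary-statistics object
#'
#' Bundles per-SNP association z-scores with an LD (correlation) matrix and
#' the GWAS sample size — the minimum input for the summary-statistics path
#' of the joint association test.
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param z Numeric vector of per-SNP association z-scores, aligned to
#'   `snp_ids`. Assumed to be on the standardized-genotype scale.
#' @param ld Symmetric correlation matrix aligned to `snp_ids`
#'   (unit diagonal within `1e-6`; entries in \[-1, 1\]).
#' @param n GWAS sample size (> 1).
#'
#' @return An object of class `gwas_summary`: a list with elements
#'   `snp_ids`, `z`, `ld`, `n`.
#' @export
gwas_summary <- function(snp_ids, z, ld, n) {
  snp_ids <- as.character(snp_ids)
  z <- as.numeric(z)
  ld <- as.matrix(ld)
  if (length(n) != 1L || !is.finite(n) || n <= 1) {
    abort_arg("`n` must be a single sample size greater than 1.")
  }
  if (length(z) != length(snp_ids)) {
    abort_format("`z` and `snp_ids` must have equal length.")
  }
  if (nrow(ld) != ncol(ld) || nrow(ld) != length(z)) {
    abort_format("`ld` must be square with dimension length(z).")
  }
  if (max(abs(ld - t(ld))) > 1e-8) {
    abort_format("`ld` is not symmetric (max |ld - t(ld)| > 1e-8).")
  }
  if (max(abs(diag(ld) - 1)) > 1e-6) {
    abort_validation("`ld` diagonal must be 1 (correlation matrix).")
  }
  if (max(abs(ld)) > 1 + 1e-8) {
    abort_validation("`ld` entries must lie in [-1, 1].")
  }
  dimnames(ld) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, z = stats::setNames(z, snp_ids),
                 ld = ld, n = as.numeric(n)),
            class = "gwas_summary")
}

#' @export
print.gwas_summary <- function(x, ...) {
  cat(sprintf("<gwas_summary> %d SNPs, n = %g\n", length(x$snp_ids), x$n))
  invisible(x)
}

#' Read GWAS summary statistics from delimited files
#'
#' @param z_path Tab-separated file with columns `snp_id` and `z`.
#' @param ld_path Tab-separated dense square LD matrix with SNP ids as the
#'   header row and as a leading `snp_id` column. Rows/columns may appear in
#'   any order; they are aligned to the z-score table.
#' @param n GWAS sample size.
#' @return A [gwas_summary()] object aligned to the z-score SNP order.
#' @export
read_gwas_summary <- function(z_path, ld_path, n) {
  ztbl <- readr::read_tsv(z_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("snp_id", "z") %in% names(ztbl))) {
    abort_format("z-score file must have columns `snp_id` and `z`.")
  }
  ldtbl <- readr::read_tsv(ld_path, show_col_types = FALSE, progress = FALSE)
  if (names(ldtbl)[1] != "snp_id") {
    abort_format("LD file must have a leading `snp_id` column.")
  }
  ld_ids <- as.character(ldtbl$snp_id)
  ld <- as.matrix(ldtbl[, -1, drop = FALSE])
  rownames(ld) <- ld_ids
  snp_ids <- as.character(ztbl$snp_id)
  missing <- setdiff(snp_ids, intersect(ld_ids, colnames(ld)))
  if (length(missing) > 0) {
    abort_alignment(sprintf(
      "SNP(s) present in z-scores but absent from LD: %s",
      paste(missing, collapse = ", ")))
  }
  ld <- ld[snp_ids, snp_ids, drop = FALSE]
  gwas_summary(snp_ids, ztbl$z, ld, n)
}

#' Write GWAS summary statistics to delimited files
#'
#' @param gs A [gwas_summary()] object.
#' @param z_path,ld_path Output paths (tab-separated; see
#'   [read_gwas_summary()] for the layout).
#' @return `z_path`, invisibly.
#' @export
write_gwas_summary <- function(gs, z_path, ld_path) {
  stopifnot(inherits(gs, "gwas_summary"))
  readr::write_tsv(tibble::tibble(snp_id = gs$snp_ids, z = unname(gs$z)),
                   z_path, progress = FALSE)
  ldtbl <- tibble::as_tibble(gs$ld)
  ldtbl <- dplyr::bind_cols(tibble::tibble(snp_id = gs$snp_ids), ldtbl)
  readr::write_tsv(ldtbl, ld_path, progress = FALSE)
  invisible(z_path)
}

#' Validate individual-level data for the one-sample design
#'
#' @param G Genotype matrix (individuals x SNPs, dosages 0-2).
#' @param Y Trait vector, centered to mean zero within `tol`.
#' @param E,P Optional centered molecular trait vectors.
#' @param tol Tolerance for the centering check.
#' @return Invisibly, a list with the validated components.
#' @export
validate_individual_data <- function(G, Y, E = NULL, P = NULL, tol = 1e-6) {
  G <- as.matrix(G)
  if (nrow(G) != length(Y)) {
    abort_validation("`G` and `Y` must have matching row counts.")
  }
  for (nm in c("Y", "E", "P")) {
    v <- switch(nm, Y = Y, E = E, P = P)
    if (is.null(v)) next
    if (length(v) != nrow(G)) {
      abort_validation(sprintf("`%s` length must equal nrow(G).", nm))
    }
    if (abs(mean(v)) > tol * max(1, sd(v))) {
      abort_validation(sprintf(
        "`%s` must be centered to mean zero (phenotypes are pre-centered).",
        nm))
    }
  }
  invisible(list(G = G, Y = Y, E = E, P = P))
}
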