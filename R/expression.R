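#' Differential-expression classification parameters
#'
#' Upregulated means linear fold change at least `up_min_fc` with FDR
#' at most `fdr_max`; downregulated means log2 fold change below
#' `down_max_log2fc` (default 0, i.e. any decrease) with the same FDR
#' gate, or `FC <= 1/up_min_fc` when `symmetric_down = TRUE`.
#'
#' @param up_min_fc Minimum linear fold change for upregulation.
#' @param down_max_log2fc Log2 threshold below which a gene counts as
#'   downregulated.
#' @param fdr_max FDR gate applied to both classes.
#' @param symmetric_down Use the symmetric rule `FC <= 1/up_min_fc`
#'   for downregulation instead of the log2 threshold.
#' @return A named list of class `de_params`.
#' @export
de_params <- function(up_min_fc = 4, down_max_log2fc = 0, fdr_max = 0.01,
                      symmetric_down = FALSE) {
  stopifnot(up_min_fc >= 1, fdr_max > 0, fdr_max <= 1)
  structure(list(up_min_fc = up_min_fc, down_max_log2fc = down_max_log2fc,
                 fdr_max = fdr_max, symmetric_down = symmetric_down),
            class = "de_params")
}

#' Read a differential-expression table
#'
#' TSV with columns gene_id, fold change (linear or log2, declared via
#' `scale`) and FDR. Fold changes are normalised to the linear scale
#' internally.
#'
#' @param path File path.
#' @param scale Scale of the fold-change column in the file.
#' @return Tibble with `gene_id`, `fold_change` (linear), `fdr`.
#' @export
read_de_table <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  x <- readr::read_tsv(path, col_types = "cdd", progress = FALSE,
                       col_names = c("gene_id", "fold_change", "fdr"))
  if (anyNA(x$fdr)) rlang::abort("DE table: missing FDR values")
  if (nrow(x) > 0 && (any(x$fdr < 0) || any(x$fdr > 1))) {
    rlang::abort("DE table: FDR outside [0, 1]")
  }
  if (scale == "log2") x$fold_change <- 2^x$fold_change
  if (nrow(x) > 0 && any(x$fold_change <= 0)) {
    rlang::abort("DE table: linear fold change must be > 0")
  }
  x
}

#' Classify genes as up-, down- or unchanged
#'
#' A pure function of fold change, FDR and the thresholds in
#' [de_params()]; `up` and `down` are mutually exclusive because
#' `up_min_fc >= 1`.
#'
#' @param de DE tibble with `fold_change` (linear) and `fdr`.
#' @param params [de_params()].
#' @return `de` with a `de_class` column (`up`/`down`/`unchanged`).
#' @export
classify_de <- function(de, params = de_params()) {
  down_rule <- if (params$symmetric_down) {
    de$fold_change <= 1 / params$up_min_fc
  } else {
    log2(de$fold_change) < params$down_max_log2fc
  }
  dplyr::mutate(de, de_class = dplyr::case_when(
    .data$fold_change >= params$up_min_fc & .data$fdr <= params$fdr_max ~ "up",
    down_rule & .data$fdr <= params$fdr_max ~ "down",
    TRUE ~ "unchanged"))
}

#' Restrict a DE table to a curated gene panel
#'
#' Order-preserving filter to the panel's gene ids, with per-class
#' counts attached as attribute `"class_counts"`.
#'
#' @param de Classified DE tibble.
#' @param panel Character vector of unique gene ids.
#' @return Filtered tibble.
#' @export
subset_panel <- function(de, panel) {
  if (length(panel) == 0) rlang::abort("gene panel is empty")
  if (anyDuplicated(panel)) rlang::abort("gene panel contains duplicate ids")
  out <- de[de$gene_id %in% panel, , drop = FALSE]
  counts <- if ("de_class" %in% names(out)) {
    dplyr::count(out, .data$de_class, name = "n")
  } else {
    tibble::tibble(de_class = character(), n = integer())
  }
  attr(out, "class_counts") <- counts
  out
}

#' Read a gene panel (one id per line)
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_panel <- function(path) {
  ids <- readr::read_lines(path)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) rlang::abort("gene panel contains duplicate ids")
  ids
}
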