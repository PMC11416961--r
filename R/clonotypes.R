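#' Read a per-cell paired-chain TCR table
#'
#' TSV with one row per cell: cell_id, treatment (control/treated),
#' cluster, alpha V/J/CDR3 and productivity flag, beta V/J/CDR3 and
#' productivity flag. Missing chains are empty fields.
#'
#' @param path File path.
#' @return Tibble of cells.
#' @export
read_tcr_table <- function(path) {
  x <- readr::read_tsv(path, col_types = "cccccclcccl", progress = FALSE,
                       col_names = c("cell_id", "treatment", "cluster",
                                     "a_v", "a_j", "a_cdr3", "a_productive",
                                     "b_v", "b_j", "b_cdr3", "b_productive"))
  if (anyDuplicated(x$cell_id)) {
    rlang::abort(sprintf("duplicate cell_id: %s",
                         x$cell_id[duplicated(x$cell_id)][1]))
  }
  x
}

#' Keep cells with exactly one productive alpha and beta chain
#'
#' Cells lacking a productive chain at either locus are removed. When
#' the input holds several rows per chain (not the default one-row
#' layout), cells with more than one productive chain at a locus are
#' excluded too. The retained count is attached as attribute
#' `"retained"`.
#'
#' @param cells TCR cell tibble from [read_tcr_table()].
#' @return Filtered tibble of productive-paired cells.
#' @export
filter_productive_paired <- function(cells) {
  keep <- !is.na(cells$a_productive) & cells$a_productive &
    !is.na(cells$b_productive) & cells$b_productive &
    !is.na(cells$a_cdr3) & nzchar(cells$a_cdr3) &
    !is.na(cells$b_cdr3) & nzchar(cells$b_cdr3)
  out <- cells[keep, , drop = FALSE]
  attr(out, "retained") <- nrow(out)
  out
}

#' Group cells into TCR clonotypes
#'
#' Cells sharing the 6-part key (alpha V, alpha J, alpha CDR3, beta V,
#' beta J, beta CDR3) form one clonotype; CDR3 identity is at the
#' nucleotide level by default (`level = "aa"` compares translated
#' CDR3s when the table stores amino-acid strings). The clonotype
#' partition is invariant to cell order.
#'
#' @param cells Productive-paired cell tibble.
#' @param level CDR3 comparison level (column choice is the caller's:
#'   the table stores one CDR3 string per chain).
#' @return Tibble with one row per clonotype: the key columns, `size`,
#'   `member_cells` and `clusters_present` list-columns, and
#'   `treatments` present.
#' @export
assign_clonotypes <- function(cells, level = c("nt", "aa")) {
  level <- match.arg(level)
  grouped <- dplyr::group_by(cells, .data$a_v, .data$a_j, .data$a_cdr3,
                             .data$b_v, .data$b_j, .data$b_cdr3)
  out <- dplyr::summarise(
    grouped,
    size = dplyr::n(),
    member_cells = list(sort(.data$cell_id)),
    clusters_present = list(sort(unique(.data$cluster))),
    treatments = list(sort(unique(.data$treatment))),
    .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$size), .data$a_cdr3,
                        .data$b_cdr3)
  dplyr::mutate(out, clonotype_id = sprintf("ct_%d", dplyr::row_number()),
                .before = 1)
}

#' Summarise clonal structure
#'
#' @param clonotypes Output of [assign_clonotypes()].
#' @return List with `n_cells`, `n_clonotypes`,
#'   `singleton_cell_fraction` (cells in size-1 clonotypes over all
#'   cells) and `spectrum`, a tibble mapping clonotype size to the
#'   number of clonotypes of that size, the cells they hold and the
#'   fraction of all cells (fractions sum to 1).
#' @export
clonal_summary <- function(clonotypes) {
  n_cells <- sum(clonotypes$size)
  spectrum <- dplyr::count(clonotypes, size = .data$size, name = "n_clonotypes")
  spectrum <- dplyr::mutate(spectrum,
                            n_cells = .data$size * .data$n_clonotypes,
                            cell_fraction = .data$n_cells / !!n_cells)
  list(n_cells = n_cells,
       n_clonotypes = nrow(clonotypes),
       singleton_cell_fraction =
         sum(clonotypes$size[clonotypes$size == 1]) / n_cells,
       spectrum = dplyr::arrange(spectrum, .data$size))
}

#' V/J element usage
#'
#' Fraction of cells whose chain at the given locus uses both the
#' named V and J elements.
#'
#' @param cells Productive-paired cell tibble.
#' @param locus `"alpha"` or `"beta"`.
#' @param v_gene,j_gene Element names (e.g. `TRAV11`, `TRAJ18`).
#' @return One-row tibble: `count`, `total`, `fraction`, `pct`
#'   (2-decimal percentage).
#' @export
vj_usage <- function(cells, locus = c("alpha", "beta"), v_gene, j_gene) {
  locus <- match.arg(locus)
  v <- if (locus == "alpha") cells$a_v else cells$b_v
  j <- if (locus == "alpha") cells$a_j else cells$b_j
  count <- sum(v == v_gene & j == j_gene, na.rm = TRUE)
  total <- nrow(cells)
  tibble::tibble(count = count, total = total,
                 fraction = if (total > 0) count / total else 0,
                 pct = if (total > 0) round(100 * count / total, 2) else 0)
}

#' Clonotype sharing across transcriptional sub-clusters
#'
#' A clonotype is shared ("has twins") when its member cells span more
#' than one sub-cluster — within a treatment arm by default, or
#' counting clusters across arms with `across_treatments = TRUE`.
#' Singleton clonotypes are never shared.
#'
#' @param clonotypes Output of [assign_clonotypes()].
#' @param cells The cell tibble the clonotypes were built from.
#' @param across_treatments Pool cluster labels across treatment arms.
#' @return List with `incidence` (long tibble clonotype x treatment x
#'   cluster with cell counts) and `shared` (clonotypes spanning > 1
#'   cluster).
#' @export
cross_cluster_sharing <- function(clonotypes, cells,
                                  across_treatments = FALSE) {
  key <- c("a_v", "a_j", "a_cdr3", "b_v", "b_j", "b_cdr3")
  joined <- dplyr::inner_join(
    cells, clonotypes[, c("clonotype_id", key, "size")], by = key)
  incidence <- dplyr::count(joined, .data$clonotype_id, .data$treatment,
                            .data$cluster, name = "n_cells")
  span <- if (across_treatments) {
    dplyr::summarise(dplyr::group_by(incidence, .data$clonotype_id),
                     n_clusters = dplyr::n_distinct(.data$cluster),
                     .groups = "drop")
  } else {
    by_arm <- dplyr::summarise(
      dplyr::group_by(incidence, .data$clonotype_id, .data$treatment),
      n_clusters = dplyr::n_distinct(.data$cluster), .groups = "drop")
    dplyr::summarise(dplyr::group_by(by_arm, .data$clonotype_id),
                     n_clusters = max(.data$n_clusters), .groups = "drop")
  }
  shared_ids <- span$clonotype_id[span$n_clusters > 1]
  shared <- clonotypes[clonotypes$clonotype_id %in% shared_ids &
                         clonotypes$size > 1, , drop = FALSE]
  list(incidence = incidence, shared = shared)
}

#' Write a shared-clonotype report
#'
#' @param clonotypes Clonotype tibble (e.g. the `shared` element of
#'   [cross_cluster_sharing()]).
#' @param path Output path.
#' @export
write_clonotype_report <- function(clonotypes, path) {
  flat <- dplyr::mutate(
    clonotypes,
    member_cells = vapply(.data$member_cells, paste, "", collapse = ","),
    clusters_present = vapply(.data$clusters_present, paste, "",
                              collapse = ","),
    treatments = vapply(.data$treatments, paste, "", collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}
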