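#' Read a peak file (BED3+ or narrowPeak)
#'
#' narrowPeak input (10 columns) maps column 7 (signalValue) to
#' `signal`; the summit column is ignored. Plain BED3 peaks get
#' `signal = NA`.
#'
#' @param path File path.
#' @param assay Assay tag, one of `"OCR"`, `"H3K27ac"`, `"H3K4me3"`.
#' @return Tibble with `chrom`, `start`, `end`, `assay`, `signal`.
#' @export
read_peaks <- function(path, assay = c("OCR", "H3K27ac", "H3K4me3")) {
  assay <- match.arg(assay)
  x <- read_bed(path)
  signal <- rep(NA_real_, nrow(x))
  if ("extra4" %in% names(x)) {  # narrowPeak column 7 = signalValue
    signal <- suppressWarnings(as.numeric(x$extra4))
  }
  tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                 assay = assay, signal = signal)
}

#' Read a differential-feature table
#'
#' TSV with columns chrom, start, end, assay, direction (gain/loss),
#' fdr, gene — the output of an external differential-peak fit.
#'
#' @param path File path.
#' @return Tibble of differential features.
#' @export
read_diff_features <- function(path) {
  x <- readr::read_tsv(path, col_types = "ciiccdc", progress = FALSE,
                       col_names = c("chrom", "start", "end", "assay",
                                     "direction", "fdr", "gene"))
  if (nrow(x) > 0 && (any(x$fdr < 0) || any(x$fdr > 1))) {
    rlang::abort("diff-feature fdr outside [0, 1]")
  }
  if (nrow(x) > 0 && !all(x$direction %in% c("gain", "loss"))) {
    rlang::abort("diff-feature direction must be 'gain' or 'loss'")
  }
  x
}

#' Call active enhancers
#'
#' An active enhancer is an open chromatin region (OCR) that overlaps
#' at least one H3K27ac peak and does not overlap any promoter
#' interval. The reported interval is the OCR itself (or the union of
#' its OCR/H3K27ac intersections with `mode = "intersection"`). Each
#' enhancer is assigned a compartment — `gene_body` if it overlaps any
#' gene span, else `intergenic` — and linked to every gene whose
#' `gene_window_bp` TSS window overlaps it.
#'
#' @param ocrs Open-chromatin peak tibble (one condition).
#' @param k27ac H3K27ac peak tibble (same condition).
#' @param genes Gene-model tibble.
#' @param params [annotation_params()].
#' @param mode Report the whole OCR (default) or the OCR/H3K27ac
#'   intersection span.
#' @return Tibble of enhancers (`chrom`, `start`, `end`, `compartment`,
#'   `linked_genes` list-column, `hypo_methylated` initialised `NA`).
#' @export
call_active_enhancers <- function(ocrs, k27ac, genes,
                                  params = annotation_params(),
                                  mode = c("ocr", "intersection")) {
  mode <- match.arg(mode)
  validate_intervals(ocrs, "OCR peak")
  validate_intervals(k27ac, "H3K27ac peak")
  validate_genes(genes)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), compartment = character(),
                          linked_genes = list(),
                          hypo_methylated = logical())
  if (nrow(ocrs) == 0) return(empty)
  has_k27 <- overlaps_any(ocrs, k27ac)
  proms <- promoters_of(genes, params)
  in_prom <- overlaps_any(ocrs, proms)
  enh <- ocrs[has_k27 & !in_prom, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(enh) == 0) return(empty)
  if (mode == "intersection") {
    pairs <- overlap_pairs(enh, k27ac)
    inter <- dplyr::transmute(
      pairs,
      chrom = enh$chrom[.data$query],
      start = pmax(enh$start[.data$query], k27ac$start[.data$subject]),
      end = pmin(enh$end[.data$query], k27ac$end[.data$subject]),
      query = .data$query)
    enh <- dplyr::summarise(dplyr::group_by(inter, .data$query),
                            chrom = .data$chrom[1],
                            start = min(.data$start), end = max(.data$end),
                            .groups = "drop")[, c("chrom", "start", "end")]
  }
  in_body <- overlaps_any(enh, genes)
  wins <- tss_window(genes, params$gene_window_bp)
  hits <- overlap_pairs(enh, wins)
  linked <- rep(list(character()), nrow(enh))
  if (nrow(hits) > 0) {
    by_enh <- split(wins$gene_id[hits$subject], hits$query)
    linked[as.integer(names(by_enh))] <- lapply(by_enh, unique)
  }
  out <- dplyr::mutate(enh,
                       compartment = dplyr::if_else(in_body, "gene_body",
                                                    "intergenic"),
                       linked_genes = linked,
                       hypo_methylated = NA)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Compartment counts of an enhancer set
#'
#' Totals and percentages of gene-body versus intergenic enhancers,
#' plus the number of distinct genes linked within each compartment.
#'
#' @param enhancers Output of [call_active_enhancers()].
#' @return One-row tibble: `total`, `gene_body`, `intergenic`,
#'   `pct_gene_body`, `pct_intergenic`, `genes_gene_body`,
#'   `genes_intergenic`.
#' @export
partition_counts <- function(enhancers) {
  total <- nrow(enhancers)
  gb <- sum(enhancers$compartment == "gene_body")
  ig <- sum(enhancers$compartment == "intergenic")
  genes_in <- function(comp) {
    length(unique(unlist(
      enhancers$linked_genes[enhancers$compartment == comp])))
  }
  tibble::tibble(
    total = total, gene_body = gb, intergenic = ig,
    pct_gene_body = if (total > 0) round(100 * gb / total, 2) else 0,
    pct_intergenic = if (total > 0) round(100 * ig / total, 2) else 0,
    genes_gene_body = genes_in("gene_body"),
    genes_intergenic = genes_in("intergenic"))
}

#' Link enhancers to genes by TSS proximity
#'
#' A gene is linked to an enhancer when the enhancer overlaps the
#' gene's symmetric TSS window of the given half-width (50 kb for the
#' hypo-methylated-enhancer analysis, 100 kb for annotation).
#'
#' @param enhancers Enhancer tibble.
#' @param genes Gene-model tibble.
#' @param half_width TSS-window half-width in bp.
#' @return Long tibble (`gene_id`, `enhancer` row index, `chrom`,
#'   `start`, `end`), one row per link.
#' @export
link_enhancers_to_genes <- function(enhancers, genes, half_width) {
  validate_intervals(enhancers, "enhancer")
  wins <- tss_window(genes, half_width)
  hits <- overlap_pairs(enhancers, wins)
  tibble::tibble(gene_id = wins$gene_id[hits$subject],
                 enhancer = hits$query,
                 chrom = enhancers$chrom[hits$query],
                 start = enhancers$start[hits$query],
                 end = enhancers$end[hits$query])
}

#' Flag enhancers overlapping hypo-methylated DMRs
#'
#' Sets `hypo_methylated` true for each enhancer overlapping at least
#' one DMR with direction `hypo`; hyper-methylated DMRs do not count.
#'
#' @param enhancers Enhancer tibble.
#' @param dmrs DMR tibble carrying a `direction` column.
#' @return `enhancers` with `hypo_methylated` filled; the count and
#'   fraction flagged are attached as attribute `"hypo_summary"`.
#' @export
colocalize_enhancer_dmrs <- function(enhancers, dmrs) {
  hypo <- dmrs[dmrs$direction == "hypo", , drop = FALSE]
  flag <- if (nrow(enhancers) == 0) logical() else overlaps_any(enhancers, hypo)
  out <- dplyr::mutate(enhancers, hypo_methylated = flag)
  attr(out, "hypo_summary") <- tibble::tibble(
    n_hypo = sum(flag), total = nrow(enhancers),
    fraction = if (nrow(enhancers) > 0) sum(flag) / nrow(enhancers) else 0)
  out
}

#' Write enhancers to disk
#'
#' BED6+ with compartment and hypo-methylation flag columns.
#'
#' @param enhancers Enhancer tibble.
#' @param path Output path.
#' @export
write_enhancers <- function(enhancers, path) {
  bed <- dplyr::transmute(
    enhancers,
    chrom = .data$chrom, start = .data$start, end = .data$end,
    name = sprintf("enh_%d", dplyr::row_number()), score = 0, strand = ".",
    compartment = .data$compartment,
    hypo_methylated = dplyr::coalesce(.data$hypo_methylated, FALSE))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
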