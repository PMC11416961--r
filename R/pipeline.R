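#' Read a study directory written by [write_study()]
#'
#' @param dir Directory holding the standard file set (genes.tsv,
#'   control.cov, treated.cov, ocr/k27ac BED files per condition,
#'   diff_features.tsv, de.tsv, tcr.tsv).
#' @return List of input tibbles keyed like the in-memory study.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    genes = read_gene_models(p("genes.tsv")),
    control_sites = read_cpg_report(p("control.cov")),
    treated_sites = read_cpg_report(p("treated.cov")),
    ocr_pre = read_peaks(p("ocr_pre.bed"), "OCR"),
    ocr_post = read_peaks(p("ocr_post.bed"), "OCR"),
    k27ac_pre = read_peaks(p("k27ac_pre.bed"), "H3K27ac"),
    k27ac_post = read_peaks(p("k27ac_post.bed"), "H3K27ac"),
    diff_features = read_diff_features(p("diff_features.tsv")),
    de = read_de_table(p("de.tsv"), "linear"),
    tcr = if (file.exists(p("tcr.tsv"))) read_tcr_table(p("tcr.tsv")) else NULL)
}

#' Run the full integration pipeline
#'
#' Executes the analysis chain on a set of inputs: DMR calling,
#' merging and annotation; active-enhancer prediction per condition;
#' hypo-methylated-enhancer colocalisation and 50 kb gene linking; DE
#' classification; the per-gene mark matrix; mark-expression
#' association tests; epigenetic group labels; mark tallies; the
#' modification-burden histogram; and (when a TCR table is present)
#' the clonotype summaries. The computation is deterministic: no
#' random numbers are drawn.
#'
#' @param inputs Either the output of [simulate_study()], the output
#'   of [read_study()], or a directory path.
#' @param ann_params,dmr_pars,de_pars Parameter objects.
#' @return A list of class `epi_pipeline` with every intermediate and
#'   a `summary` list of headline statistics.
#' @export
run_pipeline <- function(inputs,
                         ann_params = annotation_params(),
                         dmr_pars = dmr_params(),
                         de_pars = de_params()) {
  if (is.character(inputs)) inputs <- read_study(inputs)
  if (!is.null(inputs$methylome)) {  # in-memory synthetic study
    inputs <- list(genes = inputs$genome$genes,
                   control_sites = inputs$methylome$control_sites,
                   treated_sites = inputs$methylome$treated_sites,
                   ocr_pre = inputs$peaks$ocr_pre,
                   ocr_post = inputs$peaks$ocr_post,
                   k27ac_pre = inputs$peaks$k27ac_pre,
                   k27ac_post = inputs$peaks$k27ac_post,
                   diff_features = inputs$peaks$diff_features,
                   de = inputs$peaks$de,
                   tcr = inputs$repertoire$cells)
  }
  genes <- inputs$genes

  dmrs <- call_dmrs(inputs$control_sites, inputs$treated_sites, dmr_pars)
  dmrs <- merge_adjacent_dmrs(dmrs, inputs$control_sites,
                              inputs$treated_sites, dmr_pars)
  dmrs <- annotate_dmrs(dmrs[dmrs$significant, , drop = FALSE],
                        genes, ann_params)

  enh_pre <- call_active_enhancers(inputs$ocr_pre, inputs$k27ac_pre,
                                   genes, ann_params)
  enh_post <- call_active_enhancers(inputs$ocr_post, inputs$k27ac_post,
                                    genes, ann_params)
  enh_post <- colocalize_enhancer_dmrs(enh_post, dmrs)
  hypo_links <- link_enhancers_to_genes(
    enh_post[enh_post$hypo_methylated, , drop = FALSE],
    genes, ann_params$enhancer_link_bp)

  de <- classify_de(inputs$de, de_pars)
  mm <- build_mark_matrix(genes, dmrs, inputs$diff_features,
                          enh_pre, enh_post, hypo_links, de)
  mm <- epigenetic_group(mm)
  assoc <- association_report(mm)
  tally <- mark_weight_tally(mm)
  burden <- modification_burden(mm)

  clonotypes <- NULL; clonal <- NULL; sharing <- NULL
  if (!is.null(inputs$tcr)) {
    paired <- filter_productive_paired(inputs$tcr)
    clonotypes <- assign_clonotypes(paired)
    clonal <- clonal_summary(clonotypes)
    sharing <- cross_cluster_sharing(clonotypes, paired)
  }

  summary <- list(
    n_genes = nrow(genes),
    n_dmrs = nrow(dmrs),
    n_dmrs_hypo = sum(dmrs$direction == "hypo"),
    n_dmrs_hyper = sum(dmrs$direction == "hyper"),
    enhancers_pre = partition_counts(enh_pre),
    enhancers_post = partition_counts(enh_post),
    n_hypo_enhancers = sum(enh_post$hypo_methylated),
    n_hypo_enhancer_genes = length(unique(hypo_links$gene_id)),
    de_counts = dplyr::count(de, .data$de_class),
    group_counts = dplyr::count(mm, .data$epi_group),
    association = assoc,
    clonal = clonal)

  structure(list(dmrs = dmrs, enhancers_pre = enh_pre,
                 enhancers_post = enh_post, hypo_links = hypo_links,
                 de = de, mark_matrix = mm, association = assoc,
                 tally = tally, burden = burden,
                 clonotypes = clonotypes, clonal = clonal,
                 sharing = sharing, summary = summary),
            class = "epi_pipeline")
}

#' @export
print.epi_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<epi_pipeline>\n")
  cat(sprintf("  genes: %d | DMRs: %d (%d hypo / %d hyper)\n",
              s$n_genes, s$n_dmrs, s$n_dmrs_hypo, s$n_dmrs_hyper))
  cat(sprintf("  enhancers pre/post: %d / %d (hypo-methylated: %d, linked genes: %d)\n",
              s$enhancers_pre$total, s$enhancers_post$total,
              s$n_hypo_enhancers, s$n_hypo_enhancer_genes))
  cat(sprintf("  DE: %s\n",
              paste(sprintf("%s=%d", s$de_counts$de_class, s$de_counts$n),
                    collapse = ", ")))
  if (!is.null(s$clonal)) {
    cat(sprintf("  clonotypes: %d over %d cells (singleton fraction %.2f%%)\n",
                s$clonal$n_clonotypes, s$clonal$n_cells,
                100 * s$clonal$singleton_cell_fraction))
  }
  invisible(x)
}

#' Human-readable report tables from a pipeline run
#'
#' @param result An `epi_pipeline` object.
#' @return Named list of tibbles with deterministic ordering:
#'   association report, group counts, mark tally, burden histogram,
#'   compartment counts, and the shared-clonotype table when present.
#' @export
pipeline_report <- function(result) {
  rep <- list(
    association = result$association,
    groups = dplyr::arrange(dplyr::count(result$mark_matrix, .data$epi_group),
                            .data$epi_group),
    mark_tally = result$tally,
    burden = result$burden$histogram,
    enhancer_partition = dplyr::bind_rows(
      pre = partition_counts(result$enhancers_pre),
      post = partition_counts(result$enhancers_post), .id = "condition"))
  if (!is.null(result$sharing)) rep$shared_clonotypes <- result$sharing$shared
  rep
}

#' Write pipeline outputs to a directory
#'
#' DMR BED/TSV, enhancer BEDs, mark-matrix TSV, association TSV, group
#' TSV, burden TSV, clonotype report, and a JSON summary of headline
#' statistics.
#'
#' @param result An `epi_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_dmrs(result$dmrs, p("dmrs.bed"), p("dmrs.tsv"))
  write_enhancers(result$enhancers_pre, p("enhancers_pre.bed"))
  write_enhancers(result$enhancers_post, p("enhancers_post.bed"))
  mm <- result$mark_matrix
  readr::write_tsv(mm, p("mark_matrix.tsv"))
  readr::write_tsv(result$association, p("association.tsv"))
  readr::write_tsv(dplyr::count(mm, .data$epi_group), p("groups.tsv"))
  readr::write_tsv(result$burden$histogram, p("burden.tsv"))
  if (!is.null(result$clonotypes)) {
    write_clonotype_report(result$clonotypes, p("clonotypes.tsv"))
  }
  s <- result$summary
  s$enhancers_pre <- as.list(s$enhancers_pre)
  s$enhancers_post <- as.list(s$enhancers_post)
  jsonlite::write_json(s, p("summary.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
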