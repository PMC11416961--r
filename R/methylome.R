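#' DMR-calling parameters
#'
#' A region is differentially methylated when it holds at least
#' `min_cpg` CpG sites covered in both groups, shows at least a
#' `min_fold` change in mean methylation level between groups (in
#' either direction) and a two-sided Fisher exact P value on the
#' pooled read counts of at most `alpha`. Benjamini-Hochberg q-values
#' are computed over all tested candidate regions; the significant set
#' uses `q_threshold`. Consecutive CpGs further apart than
#' `max_gap_bp` start a new candidate region.
#'
#' @param min_cpg Minimum CpG sites per region.
#' @param min_fold Minimum fold change of mean methylation level.
#' @param alpha Fisher P threshold.
#' @param q_threshold BH q threshold for the significant set.
#' @param max_gap_bp Maximum distance between consecutive CpGs in one
#'   candidate region.
#' @return A named list of class `dmr_params`.
#' @export
dmr_params <- function(min_cpg = 5, min_fold = 2, alpha = 0.05,
                       q_threshold = 0.05, max_gap_bp = 300) {
  stopifnot(min_cpg >= 1, min_fold >= 1,
            alpha > 0, alpha <= 1, q_threshold > 0, q_threshold <= 1,
            max_gap_bp >= 0)
  structure(list(min_cpg = min_cpg, min_fold = min_fold, alpha = alpha,
                 q_threshold = q_threshold, max_gap_bp = max_gap_bp),
            class = "dmr_params")
}

#' Read a per-cytosine bisulfite count report
#'
#' Tab-separated Bismark-coverage-style dialect: chrom, 1-based
#' position, strand, methylated count, unmethylated count, and an
#' optional sixth context column (CpG/CHG/CHH). Positions are
#' converted to 0-based; `total` is methylated + unmethylated. When a
#' context column is present only rows matching `context` are kept.
#'
#' @param path File path.
#' @param context Cytosine context to retain when the file carries a
#'   context column (default `"CpG"`).
#' @return Tibble with `chrom`, `pos` (0-based), `strand`, `meth`,
#'   `total`.
#' @export
read_cpg_report <- function(path, context = "CpG") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), meth = integer(),
                          total = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 5)) {
    rlang::abort(sprintf("CpG report parse error at line %d: fewer than 5 columns",
                         which(nf < 5)[1]))
  }
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  meth <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
  unmeth <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  bad <- which(is.na(pos1) | is.na(meth) | is.na(unmeth) |
                 meth < 0 | unmeth < 0 | pos1 < 1)
  if (length(bad) > 0) {
    rlang::abort(sprintf("CpG report parse error at line %d: negative or non-integer field",
                         bad[1]))
  }
  out <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1),
                        pos = pos1 - 1L,
                        strand = vapply(fields, `[[`, "", 3),
                        meth = meth,
                        total = meth + unmeth)
  if (any(nf >= 6)) {
    ctx <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else context, "")
    out <- out[ctx == context, , drop = FALSE]
  }
  out
}

#' Per-site methylation level
#'
#' The methylation level of a cytosine is the number of reads
#' supporting methylation divided by the total reads covering it;
#' sites with zero coverage get `NA` and are excluded from region
#' means downstream.
#'
#' @param sites CpG count tibble from [read_cpg_report()].
#' @return The input with a `level` column in `[0, 1]` (or `NA`).
#' @export
methylation_level <- function(sites) {
  stopifnot(all(c("meth", "total") %in% names(sites)))
  if (nrow(sites) > 0 && any(sites$meth > sites$total)) {
    rlang::abort("meth count exceeds total count")
  }
  dplyr::mutate(sites,
                level = dplyr::if_else(.data$total > 0,
                                       .data$meth / .data$total, NA_real_))
}

# pool replicate rows at the same (chrom, pos) by summing counts
pool_sites <- function(sites) {
  dplyr::summarise(dplyr::group_by(sites, .data$chrom, .data$pos),
                   meth = sum(.data$meth), total = sum(.data$total),
                   .groups = "drop")
}

# site-level join of the two groups restricted to positions covered in
# both, with a candidate-region id per run of nearby CpGs
candidate_sites <- function(control_sites, treated_sites, params) {
  ctl <- pool_sites(control_sites)
  trt <- pool_sites(treated_sites)
  joint <- dplyr::inner_join(ctl, trt, by = c("chrom", "pos"),
                             suffix = c("_control", "_treated"))
  joint <- dplyr::filter(joint, .data$total_control > 0, .data$total_treated > 0)
  joint <- dplyr::arrange(joint, .data$chrom, .data$pos)
  if (nrow(joint) == 0) {
    return(dplyr::mutate(joint, candidate_id = integer()))
  }
  joint <- dplyr::group_by(joint, .data$chrom)
  joint <- dplyr::mutate(joint,
                         new_run = c(TRUE, diff(.data$pos) > params$max_gap_bp))
  joint <- dplyr::ungroup(joint)
  dplyr::mutate(joint, candidate_id = cumsum(.data$new_run),
                new_run = NULL)
}

#' Segment CpG sites into candidate regions
#'
#' Maximal runs of consecutive CpG positions covered in both groups
#' with inter-CpG distance at most `max_gap_bp`; runs holding fewer
#' than `min_cpg` sites are discarded. Replicate rows at one position
#' are pooled by summing counts.
#'
#' @param control_sites,treated_sites CpG count tibbles.
#' @param params [dmr_params()].
#' @return Tibble of candidate regions (`candidate_id`, `chrom`,
#'   `start`, `end`, `n_cpg`).
#' @export
segment_candidates <- function(control_sites, treated_sites,
                               params = dmr_params()) {
  joint <- candidate_sites(control_sites, treated_sites, params)
  cand <- dplyr::summarise(
    dplyr::group_by(joint, .data$candidate_id, .data$chrom),
    start = min(.data$pos), end = max(.data$pos) + 1L,
    n_cpg = dplyr::n(), .groups = "drop")
  dplyr::arrange(dplyr::filter(cand, .data$n_cpg >= params$min_cpg),
                 .data$chrom, .data$start)
}

# region statistics for a candidate-site table already carrying
# candidate_id; one row per candidate
candidate_stats <- function(joint) {
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(joint, .data$candidate_id, .data$chrom),
    start = min(.data$pos), end = max(.data$pos) + 1L,
    n_cpg = dplyr::n(),
    unmeth_control = sum(.data$total_control - .data$meth_control),
    unmeth_treated = sum(.data$total_treated - .data$meth_treated),
    level_control = mean(.data$meth_control / .data$total_control),
    level_treated = mean(.data$meth_treated / .data$total_treated),
    meth_control = sum(.data$meth_control),
    meth_treated = sum(.data$meth_treated),
    .groups = "drop")
  stats_tbl <- dplyr::mutate(
    stats_tbl,
    fold_change = dplyr::case_when(
      level_control == 0 & level_treated == 0 ~ NA_real_,
      pmin(level_control, level_treated) == 0 ~ Inf,
      TRUE ~ pmax(level_control, level_treated) /
        pmin(level_control, level_treated)),
    direction = dplyr::if_else(.data$level_treated < .data$level_control,
                               "hypo", "hyper"))
  stats_tbl$p_value <- purrr::pmap_dbl(
    stats_tbl[, c("meth_control", "unmeth_control",
                  "meth_treated", "unmeth_treated")],
    function(meth_control, unmeth_control, meth_treated, unmeth_treated) {
      stats::fisher.test(matrix(c(meth_control, meth_treated,
                                  unmeth_control, unmeth_treated), 2))$p.value
    })
  stats_tbl
}

#' Call differentially methylated regions
#'
#' Candidate regions from [segment_candidates()] are tested by pooling
#' methylated and unmethylated read counts per group over the region
#' into one 2x2 Fisher exact table (two-sided). Mean methylation
#' levels are means of per-site levels over covered sites; fold change
#' is the larger level over the smaller (infinite when exactly one
#' level is zero, no call when both are zero). Regions passing
#' `fold_change >= min_fold` and `p <= alpha` are reported, with BH
#' q-values computed across all tested candidates and a `significant`
#' flag at `q <= q_threshold`.
#'
#' @param control_sites,treated_sites CpG count tibbles.
#' @param params [dmr_params()].
#' @return Tibble of DMRs (`chrom`, `start`, `end`, `n_cpg`,
#'   `level_control`, `level_treated`, `fold_change`, `direction`,
#'   `p_value`, `q_value`, `significant`).
#' @export
call_dmrs <- function(control_sites, treated_sites, params = dmr_params()) {
  joint <- candidate_sites(control_sites, treated_sites, params)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_cpg = integer(),
                          level_control = double(), level_treated = double(),
                          fold_change = double(), direction = character(),
                          p_value = double(), q_value = double(),
                          significant = logical())
  if (nrow(joint) == 0) return(empty)
  keep <- dplyr::count(joint, .data$candidate_id)
  keep <- keep$candidate_id[keep$n >= params$min_cpg]
  joint <- dplyr::filter(joint, .data$candidate_id %in% keep)
  if (nrow(joint) == 0) return(empty)
  cand <- candidate_stats(joint)
  cand$q_value <- stats::p.adjust(cand$p_value, method = "BH")
  cand <- dplyr::filter(cand,
                        !is.na(.data$fold_change),
                        .data$fold_change >= params$min_fold,
                        .data$p_value <= params$alpha)
  cand <- dplyr::mutate(cand,
                        significant = .data$q_value <= params$q_threshold)
  dmr_cols <- c("chrom", "start", "end", "n_cpg", "level_control",
                "level_treated", "fold_change", "direction", "p_value",
                "q_value", "significant")
  dplyr::arrange(cand[, dmr_cols], .data$chrom, .data$start)
}

#' Merge adjacent same-direction DMRs
#'
#' Consecutive DMRs on one chromosome sharing a direction are joined
#' into one continuous region when no tested candidate region lying
#' between them failed the DMR criteria — that is, when everything in
#' between (if anything) was itself differentially methylated. The
#' merged region's statistics are recomputed from the pooled counts of
#' its CpG sites, and BH q-values are recomputed over the resulting
#' region set. The operation is idempotent.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param control_sites,treated_sites The CpG count tibbles the DMRs
#'   were called from.
#' @param params [dmr_params()].
#' @return DMR tibble of the same shape as [call_dmrs()].
#' @export
merge_adjacent_dmrs <- function(dmrs, control_sites, treated_sites,
                                params = dmr_params()) {
  if (nrow(dmrs) <= 1) return(dmrs)
  dmrs <- dplyr::arrange(dmrs, .data$chrom, .data$start)
  joint <- candidate_sites(control_sites, treated_sites, params)
  keep <- dplyr::count(joint, .data$candidate_id)
  joint <- dplyr::filter(joint, .data$candidate_id %in%
                           keep$candidate_id[keep$n >= params$min_cpg])
  cand <- candidate_stats(joint)
  cand <- dplyr::mutate(
    cand,
    passed = !is.na(.data$fold_change) &
      .data$fold_change >= params$min_fold &
      .data$p_value <= params$alpha)

  # group consecutive DMRs: same chrom, same direction, and no failed
  # tested candidate strictly between the two regions
  n <- nrow(dmrs)
  new_group <- logical(n); new_group[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    prev <- dmrs[i - 1, ]; cur <- dmrs[i, ]
    blocked <- TRUE
    if (cur$chrom == prev$chrom && cur$direction == prev$direction) {
      between <- dplyr::filter(cand, .data$chrom == cur$chrom,
                               .data$start >= prev$end,
                               .data$end <= cur$start)
      blocked <- any(!between$passed)
    }
    new_group[i] <- blocked
  }
  grp <- cumsum(new_group)
  if (all(table(grp) == 1)) return(dmrs)

  merged <- purrr::map_dfr(split(seq_len(n), grp), function(idx) {
    block <- dmrs[idx, ]
    region_sites <- dplyr::filter(joint,
                                  .data$chrom == block$chrom[1],
                                  .data$pos >= min(block$start),
                                  .data$pos < max(block$end))
    region_sites$candidate_id <- 1L
    candidate_stats(region_sites)[, c("chrom", "start", "end", "n_cpg",
                                      "level_control", "level_treated",
                                      "fold_change", "direction", "p_value")]
  })
  merged$q_value <- stats::p.adjust(merged$p_value, method = "BH")
  merged <- dplyr::mutate(merged,
                          significant = .data$q_value <= params$q_threshold)
  dplyr::arrange(merged, .data$chrom, .data$start)
}

#' Annotate DMRs to genomic compartments
#'
#' Applies [classify_location()] to each DMR: gene body, promoter or
#' intergenic, with linked gene ids.
#'
#' @param dmrs DMR tibble.
#' @param genes Gene-model tibble.
#' @param params [annotation_params()].
#' @return `dmrs` with `location` and `linked_genes` columns.
#' @export
annotate_dmrs <- function(dmrs, genes, params = annotation_params()) {
  classify_location(dmrs, genes, params)
}

#' Write DMRs to disk
#'
#' Writes a BED6+ file (chrom, start, end, name, -log10 q, direction)
#' next to a full TSV with every DMR column.
#'
#' @param dmrs DMR tibble.
#' @param bed_path,tsv_path Output paths.
#' @export
write_dmrs <- function(dmrs, bed_path, tsv_path) {
  bed <- dplyr::transmute(dmrs,
                          chrom = .data$chrom, start = .data$start,
                          end = .data$end,
                          name = sprintf("dmr_%d", dplyr::row_number()),
                          score = round(-log10(pmax(.data$q_value, 1e-300)), 3),
                          strand = ".", direction = .data$direction)
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  flat <- dmrs
  if ("linked_genes" %in% names(flat)) {
    flat$linked_genes <- vapply(flat$linked_genes, paste, "", collapse = ",")
  }
  readr::write_tsv(flat, tsv_path)
  invisible(bed_path)
}
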