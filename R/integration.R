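as_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) rlang::abort("expected a 2x2 table")
  if (any(x < 0) || any(x != round(x))) {
    rlang::abort("2x2 table cells must be non-negative integers")
  }
  storage.mode(x) <- "double"
  x
}

new_epi_test <- function(method, table, statistic, p_two, direction_positive,
                         sided) {
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)  # Inf/NaN allowed for zero cells
  or_haldane <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  p_one <- if (direction_positive) p_two / 2 else 1 - p_two / 2
  structure(list(method = method, table = table, statistic = statistic,
                 p_two_sided = p_two, p_one_sided = p_one,
                 odds_ratio = or, odds_ratio_haldane = or_haldane,
                 direction_positive = direction_positive, sided = sided),
            class = "epi_test")
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with df = 1 and no Yates continuity correction
#' by default. The one-sided P value is half the two-sided P when the
#' observed association runs in the tested direction (enrichment of
#' the first-row/first-column cell relative to independence), and
#' `1 - p/2` otherwise. Both sidednesses are always carried in the
#' result.
#'
#' @param x 2x2 matrix (or coercible) of non-negative integer counts.
#' @param sided `"one"` or `"two"` — which P value [glance()] reports
#'   as `p.value`.
#' @param correct Apply the Yates continuity correction.
#' @return An object of class `epi_test`; see [tidy.epi_test()].
#' @export
chi_square_2x2 <- function(x, sided = c("one", "two"), correct = FALSE) {
  sided <- match.arg(sided)
  x <- as_2x2(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    rlang::abort("chi-square undefined: zero row or column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(x, correct = correct))
  expected11 <- sum(x[1, ]) * sum(x[, 1]) / sum(x)
  new_epi_test("chi-square", x, unname(ht$statistic),
               unname(ht$p.value), x[1, 1] >= expected11, sided)
}

#' Fisher exact test of a 2x2 contingency table
#'
#' Exact hypergeometric P; the two-sided P value sums all tables (at
#' fixed margins) no more likely than the observed one
#' (minimum-likelihood rule). One-sided P follows the same halving
#' convention as [chi_square_2x2()] by default, or the exact
#' upper-tail P with `one_sided = "exact"`.
#'
#' @inheritParams chi_square_2x2
#' @param one_sided `"half"` (two-sided/2 in the observed direction)
#'   or `"exact"` (hypergeometric tail).
#' @return An object of class `epi_test`.
#' @export
fisher_2x2 <- function(x, sided = c("one", "two"),
                       one_sided = c("half", "exact")) {
  sided <- match.arg(sided); one_sided <- match.arg(one_sided)
  x <- as_2x2(x)
  ht <- stats::fisher.test(x)
  expected11 <- sum(x[1, ]) * sum(x[, 1]) / max(sum(x), 1)
  out <- new_epi_test("fisher", x, NA_real_, unname(ht$p.value),
                      x[1, 1] >= expected11, sided)
  if (one_sided == "exact") {
    out$p_one_sided <- stats::fisher.test(x, alternative = "greater")$p.value
  }
  out
}

#' @export
print.epi_test <- function(x, ...) {
  cat(sprintf("<epi_test: %s>\n", x$method))
  print(x$table)
  cat(sprintf("statistic = %s, two-sided P = %.4g, one-sided P = %.4g\n",
              format(x$statistic, digits = 4), x$p_two_sided, x$p_one_sided))
  cat(sprintf("odds ratio = %.4g (Haldane %.4g)\n",
              x$odds_ratio, x$odds_ratio_haldane))
  invisible(x)
}

#' Tidy a 2x2 association test
#'
#' @param x An `epi_test` object.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with the statistic, both
#'   P values, the odds ratio (with Haldane-Anscombe correction
#'   alongside) and the observed direction; `glance()` returns the
#'   same with `p.value` set by the object's `sided` setting.
#' @export
tidy.epi_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_one_sided = x$p_one_sided, p_two_sided = x$p_two_sided,
                 odds_ratio = x$odds_ratio,
                 odds_ratio_haldane = x$odds_ratio_haldane,
                 direction_positive = x$direction_positive)
}

#' @rdname tidy.epi_test
#' @export
glance.epi_test <- function(x, ...) {
  dplyr::mutate(tidy(x),
                p.value = if (x$sided == "one") x$p_one_sided else x$p_two_sided)
}

mark_names <- c("hypo_gene_body", "hypo_promoter", "hypo_intergenic",
                "hyper_gene_body", "hyper_promoter", "hyper_intergenic",
                "diff_ocr_gain", "k27ac_gain", "k27ac_loss",
                "k4me3_gain", "k4me3_loss",
                "enhancer_pre", "enhancer_post", "hypo_enhancer_50kb")

dmr_mark_genes <- function(annotated_dmrs, dir, loc) {
  if (is.null(annotated_dmrs) || nrow(annotated_dmrs) == 0) return(character())
  sel <- annotated_dmrs$direction == dir & annotated_dmrs$location == loc
  unique(unlist(annotated_dmrs$linked_genes[sel]))
}

#' Build the per-gene epigenetic mark matrix
#'
#' One row per gene of the universe, one boolean column per mark. A
#' gene's mark is true iff at least one qualifying feature links to it:
#' hypo/hyper DMRs by compartment (from [annotate_dmrs()]), gained
#' differential OCRs and gained/lost H3K27ac and H3K4me3 features (from
#' the differential-feature table), active enhancers linked in the pre-
#' or post-treatment condition, and hypo-methylated enhancers linked
#' within 50 kb of the TSS. `de_class` is joined from the classified
#' DE table (genes absent there are `unchanged`).
#'
#' @param genes Gene-model tibble or character vector defining the gene
#'   universe.
#' @param annotated_dmrs DMR tibble with `direction`, `location`,
#'   `linked_genes`.
#' @param diff_features Differential-feature tibble (`assay`,
#'   `direction`, `gene`).
#' @param enhancers_pre,enhancers_post Enhancer tibbles with
#'   `linked_genes` per condition.
#' @param hypo_enhancer_links Link tibble from
#'   [link_enhancers_to_genes()] run on hypo-methylated enhancers.
#' @param de Classified DE tibble.
#' @return Tibble: `gene_id`, 14 logical mark columns, `de_class`.
#' @export
build_mark_matrix <- function(genes, annotated_dmrs = NULL,
                              diff_features = NULL,
                              enhancers_pre = NULL, enhancers_post = NULL,
                              hypo_enhancer_links = NULL, de = NULL) {
  universe <- if (is.character(genes)) genes else genes$gene_id
  if (anyDuplicated(universe)) rlang::abort("duplicate gene ids in universe")
  mm <- tibble::tibble(gene_id = universe)

  check_in_universe <- function(ids, src) {
    extra <- setdiff(ids, universe)
    if (length(extra) > 0) {
      rlang::abort(sprintf("%s references gene(s) outside the universe: %s",
                           src, paste(utils::head(extra, 3), collapse = ", ")))
    }
    ids
  }

  for (dir in c("hypo", "hyper")) {
    for (loc in c("gene_body", "promoter", "intergenic")) {
      ids <- check_in_universe(dmr_mark_genes(annotated_dmrs, dir, loc),
                               "annotated DMRs")
      mm[[paste0(dir, "_", loc)]] <- universe %in% ids
    }
  }

  diff_mark <- function(assay, dir) {
    if (is.null(diff_features) || nrow(diff_features) == 0) return(character())
    check_in_universe(
      unique(diff_features$gene[diff_features$assay == assay &
                                  diff_features$direction == dir]),
      "differential features")
  }
  mm$diff_ocr_gain <- universe %in% diff_mark("OCR", "gain")
  mm$k27ac_gain <- universe %in% diff_mark("H3K27ac", "gain")
  mm$k27ac_loss <- universe %in% diff_mark("H3K27ac", "loss")
  mm$k4me3_gain <- universe %in% diff_mark("H3K4me3", "gain")
  mm$k4me3_loss <- universe %in% diff_mark("H3K4me3", "loss")

  enh_genes <- function(enh) {
    if (is.null(enh) || nrow(enh) == 0) return(character())
    check_in_universe(unique(unlist(enh$linked_genes)), "enhancers")
  }
  mm$enhancer_pre <- universe %in% enh_genes(enhancers_pre)
  mm$enhancer_post <- universe %in% enh_genes(enhancers_post)
  hypo_enh <- if (is.null(hypo_enhancer_links) ||
                  nrow(hypo_enhancer_links) == 0) {
    character()
  } else {
    check_in_universe(unique(hypo_enhancer_links$gene_id),
                      "hypo-enhancer links")
  }
  mm$hypo_enhancer_50kb <- universe %in% hypo_enh

  if (is.null(de)) {
    mm$de_class <- "unchanged"
  } else {
    mm <- dplyr::left_join(mm, de[, c("gene_id", "de_class")], by = "gene_id")
    mm$de_class <- dplyr::coalesce(mm$de_class, "unchanged")
  }
  mm
}

#' Mark-expression association report
#'
#' For each mark column, builds the 2x2 table comparing marked versus
#' unmarked genes within the upregulated and downregulated sets —
#' `[[up & mark, up & !mark], [down & mark, down & !mark]]` — and
#' tests it. Proportions are percentages rounded to 2 decimals. P
#' values are `NA` when a margin is zero (no up or no down genes, or
#' the mark is constant).
#'
#' @param mm Mark matrix from [build_mark_matrix()].
#' @param marks Mark columns to report (default: all present).
#' @param test `"chisq"` (default) or `"fisher"`.
#' @return Tibble with one row per mark: counts, totals, percentages,
#'   statistic, one- and two-sided P, odds ratio.
#' @export
association_report <- function(mm, marks = NULL,
                               test = c("chisq", "fisher")) {
  test <- match.arg(test)
  if (is.null(marks)) marks <- intersect(mark_names, names(mm))
  up <- mm$de_class == "up"
  down <- mm$de_class == "down"
  purrr::map_dfr(marks, function(mk) {
    m <- mm[[mk]]
    tab <- matrix(c(sum(up & m), sum(down & m),
                    sum(up & !m), sum(down & !m)), 2)
    res <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NULL
           else if (test == "chisq") chi_square_2x2(tab) else fisher_2x2(tab)
    tibble::tibble(
      mark = mk,
      up_count = tab[1, 1], up_total = sum(up),
      down_count = tab[2, 1], down_total = sum(down),
      pct_up = if (sum(up) > 0) round(100 * tab[1, 1] / sum(up), 2) else NA_real_,
      pct_down = if (sum(down) > 0) round(100 * tab[2, 1] / sum(down), 2) else NA_real_,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_one_sided = if (is.null(res)) NA_real_ else res$p_one_sided,
      p_two_sided = if (is.null(res)) NA_real_ else res$p_two_sided,
      odds_ratio = if (is.null(res)) NA_real_ else res$odds_ratio,
      odds_ratio_haldane = if (is.null(res)) NA_real_ else res$odds_ratio_haldane)
  })
}

#' Classify genes into epigenetic co-occurrence groups
#'
#' Hypo-methylated genes (any compartment) are partitioned by whether
#' they also gained differential OCRs and/or H3K27ac: Group1 =
#' hypo + OCR + H3K27ac, Group2 = hypo + H3K27ac only, Group3 =
#' hypo + OCR only, Group4 = hypo only. Genes without hypo-methylation
#' are `ungrouped`. The labels partition the gene set.
#'
#' @param mm Mark matrix.
#' @return `mm` with an `epi_group` column.
#' @export
epigenetic_group <- function(mm) {
  hypo <- mm$hypo_gene_body | mm$hypo_promoter | mm$hypo_intergenic
  ocr <- mm$diff_ocr_gain
  k27 <- mm$k27ac_gain
  dplyr::mutate(mm, epi_group = dplyr::case_when(
    hypo & ocr & k27 ~ "Group1",
    hypo & !ocr & k27 ~ "Group2",
    hypo & ocr & !k27 ~ "Group3",
    hypo & !ocr & !k27 ~ "Group4",
    TRUE ~ "ungrouped"))
}

#' Per-mark occurrence tallies by expression class
#'
#' Counts, for every mark column, the upregulated and downregulated
#' genes carrying the mark — the numbers behind a radar plot of mark
#' weights.
#'
#' @param mm Mark matrix.
#' @return Tidy tibble (`mark`, `up`, `down`).
#' @export
mark_weight_tally <- function(mm) {
  marks <- intersect(mark_names, names(mm))
  purrr::map_dfr(marks, function(mk) {
    tibble::tibble(mark = mk,
                   up = sum(mm[[mk]] & mm$de_class == "up"),
                   down = sum(mm[[mk]] & mm$de_class == "down"))
  })
}

#' Modification-type burden per gene
#'
#' Collapses the mark columns into 4 modification types — any
#' methylation change, any chromatin-accessibility change, any H3K27ac
#' change, any H3K4me3 change — and counts how many types each gene
#' carries (0-4). The histogram by DE class reports absolute counts
#' and percentages (summing to 100 within each class).
#'
#' @param mm Mark matrix.
#' @return List with `per_gene` (`gene_id`, `de_class`, `burden`) and
#'   `histogram` (`de_class`, `burden`, `n`, `pct`).
#' @export
modification_burden <- function(mm) {
  meth <- mm$hypo_gene_body | mm$hypo_promoter | mm$hypo_intergenic |
    mm$hyper_gene_body | mm$hyper_promoter | mm$hyper_intergenic
  accessibility <- mm$diff_ocr_gain
  k27 <- mm$k27ac_gain | mm$k27ac_loss
  k4 <- mm$k4me3_gain | mm$k4me3_loss
  per_gene <- tibble::tibble(gene_id = mm$gene_id, de_class = mm$de_class,
                             burden = meth + accessibility + k27 + k4)
  histogram <- dplyr::count(per_gene, .data$de_class, .data$burden, name = "n")
  histogram <- dplyr::mutate(dplyr::group_by(histogram, .data$de_class),
                             pct = round(100 * .data$n / sum(.data$n), 2))
  list(per_gene = per_gene, histogram = dplyr::ungroup(histogram))
}
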