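#' Annotation parameters
#'
#' Window widths (in bp) governing promoter derivation, TSS-window
#' gene annotation and enhancer-to-gene linking. Defaults follow the
#' conventions used throughout the package: a promoter is the 2 kb
#' region upstream of the TSS, intergenic features are annotated to
#' genes within a +/-100 kb TSS window, and enhancers are linked to
#' genes within +/-50 kb of the TSS.
#'
#' @param promoter_upstream_bp Width of the promoter upstream of the TSS.
#' @param promoter_downstream_bp Width downstream of the TSS (0 keeps the
#'   promoter strictly upstream; set to 2000 for a symmetric promoter).
#' @param gene_window_bp Half-width of the TSS window used to annotate
#'   intergenic features to genes.
#' @param enhancer_link_bp Half-width of the TSS window used to link
#'   enhancers to genes.
#' @return A named list of class `annotation_params`.
#' @export
annotation_params <- function(promoter_upstream_bp = 2000,
                              promoter_downstream_bp = 0,
                              gene_window_bp = 100000,
                              enhancer_link_bp = 50000) {
  stopifnot(promoter_upstream_bp >= 0, promoter_downstream_bp >= 0,
            gene_window_bp >= 0, enhancer_link_bp >= 0)
  structure(list(promoter_upstream_bp = promoter_upstream_bp,
                 promoter_downstream_bp = promoter_downstream_bp,
                 gene_window_bp = gene_window_bp,
                 enhancer_link_bp = enhancer_link_bp),
            class = "annotation_params")
}

validate_intervals <- function(x, what = "interval") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(what, " table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    rlang::abort(paste0(what, ": chrom must be non-empty"))
  }
  if (any(x$start < 0)) rlang::abort(paste0(what, ": start must be >= 0"))
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    rlang::abort(sprintf("%s: end must exceed start (row %d: [%s, %s))",
                         what, bad, x$start[bad], x$end[bad]))
  }
  invisible(x)
}

validate_genes <- function(genes) {
  validate_intervals(genes, "gene model")
  req <- c("gene_id", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("gene model table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) > 0 && !all(genes$strand %in% c("+", "-"))) {
    rlang::abort("gene strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) rlang::abort("duplicate gene_id in gene models")
  invisible(genes)
}

#' Derive the transcription start site of each gene
#'
#' The TSS is the 0-based position of the first transcribed base:
#' `start` on the plus strand and `end - 1` on the minus strand.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return The input with a `tss` column added.
#' @export
gene_tss <- function(genes) {
  validate_genes(genes)
  dplyr::mutate(genes,
                tss = dplyr::if_else(.data$strand == "+",
                                     .data$start, .data$end - 1))
}

# interval tibble -> IRanges keyed per chromosome; 0-based half-open in,
# 1-based closed inside IRanges
as_iranges_by_chrom <- function(x) {
  split(IRanges::IRanges(start = x$start + 1L, end = x$end,
                         names = as.character(seq_len(nrow(x)))),
        x$chrom)
}

# index pairs (query row, subject row) of >=1 bp overlaps between two
# interval tibbles
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  qs <- as_iranges_by_chrom(query)
  ss <- as_iranges_by_chrom(subject)
  shared <- intersect(names(qs), names(ss))
  out <- purrr::map(shared, function(ch) {
    hits <- IRanges::findOverlaps(qs[[ch]], ss[[ch]])
    tibble::tibble(
      query = as.integer(names(qs[[ch]])[S4Vectors::queryHits(hits)]),
      subject = as.integer(names(ss[[ch]])[S4Vectors::subjectHits(hits)])
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$query, .data$subject)
}

# logical per row of `query`: does it overlap >= 1 row of `subject`?
overlaps_any <- function(query, subject) {
  hits <- overlap_pairs(query, subject)
  seq_len(nrow(query)) %in% hits$query
}

#' Pairwise interval overlap
#'
#' Two intervals overlap iff they share a chromosome and at least one
#' base under the 0-based half-open convention: `max(starts) <
#' min(ends)`. Rows of `a` and `b` are compared elementwise (recycling
#' a single-row input).
#'
#' @param a,b Interval tibbles with `chrom`, `start`, `end` columns.
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

#' Promoter intervals of gene models
#'
#' On the plus strand the promoter is
#' `[tss - promoter_upstream_bp, tss + promoter_downstream_bp)`;
#' the minus strand mirrors it in genomic coordinates. Intervals are
#' clipped at position 0.
#'
#' @param genes Gene-model tibble.
#' @param params [annotation_params()].
#' @return Tibble of promoter intervals (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`), one row per gene.
#' @export
promoters_of <- function(genes, params = annotation_params()) {
  genes <- gene_tss(genes)
  up <- params$promoter_upstream_bp
  down <- params$promoter_downstream_bp
  out <- dplyr::transmute(
    genes,
    gene_id = .data$gene_id,
    chrom = .data$chrom,
    start = dplyr::if_else(.data$strand == "+",
                           .data$tss - up, .data$tss + 1 - down),
    end = dplyr::if_else(.data$strand == "+",
                         .data$tss + down, .data$tss + 1 + up),
    strand = .data$strand
  )
  dplyr::mutate(out, start = pmax(.data$start, 0))
}

#' Symmetric TSS window
#'
#' Strand-independent interval `[tss - half_width, tss + half_width + 1)`
#' around each gene's TSS, clipped at 0. With `half_width = 0` this is
#' the single-base TSS interval.
#'
#' @param genes Gene-model tibble.
#' @param half_width Window half-width in bp.
#' @return Tibble of window intervals, one row per gene.
#' @export
tss_window <- function(genes, half_width) {
  stopifnot(half_width >= 0)
  genes <- gene_tss(genes)
  dplyr::transmute(genes,
                   gene_id = .data$gene_id,
                   chrom = .data$chrom,
                   start = pmax(.data$tss - half_width, 0),
                   end = .data$tss + half_width + 1)
}

#' Classify features as gene body, promoter or intergenic
#'
#' Applies the precedence gene_body > promoter > intergenic: a feature
#' overlapping any gene span is `gene_body` (linked to the overlapped
#' genes); otherwise a feature overlapping any promoter interval is
#' `promoter`; otherwise it is `intergenic` and linked to every gene
#' whose `gene_window_bp` TSS window overlaps it (possibly none).
#'
#' @param features Interval tibble.
#' @param genes Gene-model tibble (non-empty).
#' @param params [annotation_params()].
#' @return `features` with `location` (character) and `linked_genes`
#'   (list of character vectors) columns added.
#' @export
classify_location <- function(features, genes, params = annotation_params()) {
  validate_intervals(features, "feature")
  validate_genes(genes)
  if (nrow(genes) == 0) rlang::abort("classify_location requires >= 1 gene")
  n <- nrow(features)
  location <- rep("intergenic", n)
  linked <- rep(list(character()), n)

  body_hits <- overlap_pairs(features, genes)
  if (nrow(body_hits) > 0) {
    by_feat <- split(genes$gene_id[body_hits$subject], body_hits$query)
    idx <- as.integer(names(by_feat))
    location[idx] <- "gene_body"
    linked[idx] <- lapply(by_feat, unique)
  }

  proms <- promoters_of(genes, params)
  prom_hits <- overlap_pairs(features, proms)
  prom_hits <- prom_hits[location[prom_hits$query] != "gene_body", , drop = FALSE]
  if (nrow(prom_hits) > 0) {
    by_feat <- split(proms$gene_id[prom_hits$subject], prom_hits$query)
    idx <- as.integer(names(by_feat))
    location[idx] <- "promoter"
    linked[idx] <- lapply(by_feat, unique)
  }

  inter_idx <- which(location == "intergenic")
  if (length(inter_idx) > 0) {
    wins <- tss_window(genes, params$gene_window_bp)
    win_hits <- overlap_pairs(features[inter_idx, , drop = FALSE], wins)
    if (nrow(win_hits) > 0) {
      by_feat <- split(wins$gene_id[win_hits$subject], win_hits$query)
      idx <- inter_idx[as.integer(names(by_feat))]
      linked[idx] <- lapply(by_feat, unique)
    }
  }

  dplyr::mutate(features, location = location, linked_genes = linked)
}

#' Read and write BED intervals
#'
#' `read_bed()` parses a 3+ column tab-separated BED file (0-based
#' half-open); columns beyond the third are preserved verbatim as
#' `extra1`, `extra2`, ... so that `write_bed()` round-trips them.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    rlang::abort(sprintf("BED parse error at line %d: fewer than 3 columns",
                         which(nf < 3)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    rlang::abort(sprintf("BED parse error at line %d: non-integer coordinate",
                         which(is.na(start) | is.na(end))[1]))
  }
  out <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1),
                        start = start, end = end)
  extra_n <- max(nf) - 3L
  if (extra_n > 0) {
    for (k in seq_len(extra_n)) {
      out[[paste0("extra", k)]] <-
        vapply(fields, function(f) if (length(f) >= k + 3) f[[k + 3]] else NA_character_, "")
    }
  }
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    rlang::abort(sprintf("BED parse error at line %d: end <= start", bad[1]))
  }
  validate_intervals(out, "BED")
  out
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end",
            grep("^extra", names(x), value = TRUE))
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Six-column tab-separated table: gene_id, chrom, start, end, strand,
#' name; coordinates 0-based half-open.
#'
#' @param path File path.
#' @return Gene-model tibble.
#' @export
read_gene_models <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("gene_id", "chrom", "start", "end",
                                     "strand", "name"),
                       col_types = "cciicc", progress = FALSE)
  validate_genes(x)
  x
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble.
#' @export
write_gene_models <- function(genes, path) {
  validate_genes(genes)
  if (!"name" %in% names(genes)) genes$name <- genes$gene_id
  readr::write_tsv(genes[, c("gene_id", "chrom", "start", "end",
                             "strand", "name")],
                   path, col_names = FALSE)
  invisible(path)
}
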