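#' Synthetic-study configuration
#'
#' Defines the generative conditions for a full synthetic study: a toy
#' genome, bisulfite methylomes for a control and a treated group with
#' a tunable odds-ratio association `theta` between gene-body
#' hypo-methylation and upregulation, peak sets and differential
#' features, a differential-expression table constructed so the
#' threshold classifier recovers the intended classes exactly, and a
#' paired-chain TCR repertoire with a specified clonal-group
#' composition. All generators are pure functions of this
#' configuration; `seed` drives every random draw.
#'
#' The default DE-class sizes (162 up, 76 down) and repertoire
#' composition (325 singleton clonotypes, two 5-cell and four 2-cell
#' clonal groups among 343 productive-paired cells of 528 sequenced,
#' 333 cells using TRAV11/TRAJ18) match the study system this package
#' models; coverage (100x) and the 4-fold methylation effect are the
#' regimes the DMR caller is scored under.
#'
#' @param seed Integer seed.
#' @param n_chromosomes,n_genes Genome size.
#' @param n_up,n_down Genes per DE class (the rest are null).
#' @param theta Odds ratio of gene-body hypo-methylation given up vs
#'   down/null class.
#' @param p_down_hypo Probability a down/null gene receives a
#'   gene-body hypo region (the baseline odds `theta` acts on).
#' @param p_aux_hypo Probability of promoter and of intergenic hypo
#'   regions, class-independent (odds ratio 1).
#' @param p_hyper Probability of a gene-body hyper region,
#'   class-independent.
#' @param coverage_mean Mean reads per CpG (Poisson).
#' @param cpg_spacing_bp Distance between simulated CpGs.
#' @param n_dmr_cpg CpGs per true differential region.
#' @param control_level_shape Beta(shape1, shape2) for baseline
#'   methylation levels of ordinary gene-body CpGs.
#' @param effect_fold Methylation-level fold change in true regions
#'   (treated = control / effect_fold in hypo regions; 1 disables all
#'   true regions).
#' @param peak_density Expected enhancer-candidate peak pairs per gene.
#' @param repertoire_spec Tibble (`size`, `count`, `treatment`,
#'   `clusters`) describing clonal groups; `NULL` uses the default
#'   composition above.
#' @param n_cells,n_unproductive Productive-paired cells and
#'   additional cells lacking a productive pair.
#' @param trav11_traj18_cells Number of cells assigned the canonical
#'   TRAV11/TRAJ18 alpha pair (quota of `n_cells`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_chromosomes = 4, n_genes = 1000,
                         n_up = 162, n_down = 76,
                         theta = 6, p_down_hypo = 0.2,
                         p_aux_hypo = 0.05, p_hyper = 0.05,
                         coverage_mean = 100, cpg_spacing_bp = 100,
                         n_dmr_cpg = 10,
                         control_level_shape = c(8, 2),
                         effect_fold = 4,
                         peak_density = 1,
                         repertoire_spec = NULL,
                         n_cells = 343, n_unproductive = 185,
                         trav11_traj18_cells = NULL) {
  if (is.null(trav11_traj18_cells)) {
    trav11_traj18_cells <- round(n_cells * 333 / 343)
  }
  stopifnot(n_up + n_down <= n_genes, theta >= 1, coverage_mean > 0,
            p_down_hypo > 0, p_down_hypo < 1, effect_fold >= 1,
            n_dmr_cpg >= 1, trav11_traj18_cells <= n_cells)
  if (is.null(repertoire_spec)) {
    repertoire_spec <- tibble::tibble(
      size = c(5, 5, 2, 2, 2, 2),
      count = 1,
      treatment = c("treated", "treated", "control", "treated",
                    "control", "control"),
      clusters = list("4", "4", "4", "4", c("2", "4"), "2"))
  }
  odds_down <- p_down_hypo / (1 - p_down_hypo)
  odds_up <- theta * odds_down
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 n_genes = n_genes, n_up = n_up, n_down = n_down,
                 theta = theta, p_down_hypo = p_down_hypo,
                 p_up_hypo = odds_up / (1 + odds_up),
                 p_aux_hypo = p_aux_hypo, p_hyper = p_hyper,
                 coverage_mean = coverage_mean,
                 cpg_spacing_bp = cpg_spacing_bp, n_dmr_cpg = n_dmr_cpg,
                 control_level_shape = control_level_shape,
                 effect_fold = effect_fold, peak_density = peak_density,
                 repertoire_spec = repertoire_spec,
                 n_cells = n_cells, n_unproductive = n_unproductive,
                 trav11_traj18_cells = trav11_traj18_cells),
            class = "study_config")
}

#' Generate a toy genome of non-overlapping gene models
#'
#' Genes are laid down sequentially per chromosome with random
#' lengths (3-8 kb) and intergenic gaps (20-50 kb), alternating
#' strands at random; spans never overlap by construction.
#'
#' @param config [study_config()].
#' @return List with `genes` (gene-model tibble) and `chrom_sizes`.
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    if (n == 0) {
      return(list(genes = tibble::tibble(gene_id = character(),
                                         chrom = character(),
                                         start = integer(), end = integer(),
                                         strand = character(),
                                         name = character()),
                  chrom_sizes = tibble::tibble(chrom = character(),
                                               size = integer())))
    }
    chrom <- sprintf("chr%d", rep_len(seq_len(config$n_chromosomes), n))
    chrom <- sort(chrom)
    len <- sample(3000:8000, n, replace = TRUE)
    gap <- sample(20000:50000, n, replace = TRUE)
    start <- integer(n)
    cur <- stats::setNames(rep(10000L, config$n_chromosomes),
                           sprintf("chr%d", seq_len(config$n_chromosomes)))
    for (i in seq_len(n)) {
      start[i] <- cur[chrom[i]]
      cur[chrom[i]] <- start[i] + len[i] + gap[i]
    }
    genes <- tibble::tibble(
      gene_id = sprintf("gene%04d", seq_len(n)),
      chrom = chrom, start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      name = sprintf("Gene%04d", seq_len(n)))
    sizes <- dplyr::summarise(dplyr::group_by(genes, .data$chrom),
                              size = max(.data$end) + 50000L,
                              .groups = "drop")
    list(genes = genes, chrom_sizes = sizes)
  })
}

#' Assign ground-truth differential-expression classes
#'
#' Randomly designates `n_up` upregulated and `n_down` downregulated
#' genes and draws fold changes and FDRs that clear (or fail) the
#' default classification thresholds by construction, so
#' [classify_de()] recovers the classes exactly.
#'
#' @param config [study_config()].
#' @param genome Output of [simulate_genome()].
#' @return Tibble (`gene_id`, `fold_change`, `fdr`, `true_class`).
#' @export
simulate_de_truth <- function(config, genome) {
  withr::with_seed(config$seed + 2L, {
    ids <- genome$genes$gene_id
    n <- length(ids)
    cls <- rep("null", n)
    picked <- sample(n, config$n_up + config$n_down)
    cls[picked[seq_len(config$n_up)]] <- "up"
    cls[picked[config$n_up + seq_len(config$n_down)]] <- "down"
    fc <- dplyr::case_when(
      cls == "up" ~ 2^stats::runif(n, 2, 6),
      cls == "down" ~ 2^(-stats::runif(n, 0.5, 4)),
      TRUE ~ 2^stats::runif(n, -1.9, 1.9))
    fdr <- ifelse(cls == "null", stats::runif(n, 0.05, 1),
                  10^stats::runif(n, -6, -3))
    tibble::tibble(gene_id = ids, fold_change = fc, fdr = fdr,
                   true_class = cls)
  })
}

#' Assign ground-truth hypo/hyper methylation regions to genes
#'
#' Gene-body hypo-methylation is drawn with probability `p_up_hypo`
#' for up genes and `p_down_hypo` for down/null genes, realising the
#' configured odds ratio `theta`; promoter and intergenic hypo regions
#' and gene-body hyper regions are class-independent. With
#' `effect_fold = 1` no regions are assigned.
#'
#' @param config [study_config()].
#' @param de_truth Output of [simulate_de_truth()].
#' @return Tibble (`gene_id`, `true_class`, `hypo_body`,
#'   `hypo_promoter`, `hypo_intergenic`, `hyper_body`).
#' @export
simulate_hypo_assignment <- function(config, de_truth) {
  withr::with_seed(config$seed + 3L, {
    n <- nrow(de_truth)
    none <- config$effect_fold == 1
    p_body <- ifelse(de_truth$true_class == "up",
                     config$p_up_hypo, config$p_down_hypo)
    tibble::tibble(
      gene_id = de_truth$gene_id,
      true_class = de_truth$true_class,
      hypo_body = !none & stats::runif(n) < p_body,
      hypo_promoter = !none & stats::runif(n) < config$p_aux_hypo,
      hypo_intergenic = !none & stats::runif(n) < config$p_aux_hypo,
      hyper_body = !none & stats::runif(n) < config$p_hyper)
  })
}

# CpG sites for one region at fixed spacing; counts are
# Binomial(Poisson coverage, level) per group
sim_region_sites <- function(chrom, start, end, spacing, cov_mean,
                             level_control, level_treated) {
  pos <- seq(start, end - 1, by = spacing)
  k <- length(pos)
  cov_c <- stats::rpois(k, cov_mean)
  cov_t <- stats::rpois(k, cov_mean)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = "+",
    meth_control = stats::rbinom(k, cov_c, level_control),
    total_control = cov_c,
    meth_treated = stats::rbinom(k, cov_t, level_treated),
    total_treated = cov_t)
}

#' Generate control and treated CpG count reports
#'
#' CpGs are laid down as islands: every gene body holds a row of
#' dense clusters (`n_dmr_cpg` CpGs at `cpg_spacing_bp`, clusters
#' 1.2 kb apart so consecutive clusters are separated by more than
#' the default segmentation gap). Each cluster draws its own baseline
#' methylation from `Beta(control_level_shape)`, identical in
#' expectation between groups. Genes designated by
#' [simulate_hypo_assignment()] get one true differential cluster:
#' hypo clusters start from a high baseline (Beta(8, 2)) divided by
#' `effect_fold` in the treated group; hyper clusters start low
#' (Beta(2, 8)) and are multiplied (capped at 0.95). Promoter and
#' intergenic clusters are placed upstream of the TSS, outside gene
#' spans and promoters respectively. The ground-truth manifest lists
#' every true region with its direction and compartment.
#'
#' @param config [study_config()].
#' @param genome Output of [simulate_genome()].
#' @param de_truth Output of [simulate_de_truth()].
#' @param assignment Optional precomputed [simulate_hypo_assignment()].
#' @return List with `control_sites`, `treated_sites` (CpG count
#'   tibbles) and `truth` (manifest tibble: `chrom`, `start`, `end`,
#'   `gene_id`, `direction`, `compartment`).
#' @export
simulate_methylome <- function(config, genome, de_truth,
                               assignment = NULL) {
  if (is.null(assignment)) {
    assignment <- simulate_hypo_assignment(config, de_truth)
  }
  withr::with_seed(config$seed + 4L, {
    genes <- gene_tss(genome$genes)
    spacing <- config$cpg_spacing_bp
    span <- config$n_dmr_cpg * spacing  # one island
    sh <- config$control_level_shape
    fold <- config$effect_fold

    island <- function(chrom, start, lvl_c, lvl_t) {
      sim_region_sites(chrom, start, start + span, spacing,
                       config$coverage_mean, lvl_c, lvl_t)
    }

    pieces <- vector("list", nrow(genes))
    truth <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      a <- assignment[assignment$gene_id == g$gene_id, ]
      n_islands <- max((g$end - g$start) %/% (span + 400L), 1L)
      starts <- g$start + (seq_len(n_islands) - 1L) * (span + 400L)
      hypo_idx <- if (a$hypo_body) sample.int(n_islands, 1) else 0L
      hyper_idx <- if (a$hyper_body && n_islands > 1) {
        sample(setdiff(seq_len(n_islands), hypo_idx), 1)
      } else 0L

      regs <- vector("list", n_islands)
      tr <- list()
      for (j in seq_len(n_islands)) {
        if (j == hypo_idx) {
          lvl <- stats::rbeta(1, 8, 2)
          regs[[j]] <- island(g$chrom, starts[j], lvl, lvl / fold)
          if (fold > 1) {
            tr <- c(tr, list(tibble::tibble(
              chrom = g$chrom, start = starts[j],
              end = starts[j] + span, gene_id = g$gene_id,
              direction = "hypo", compartment = "gene_body")))
          }
        } else if (j == hyper_idx) {
          lvl <- stats::rbeta(1, 2, 8)
          regs[[j]] <- island(g$chrom, starts[j], lvl,
                              min(lvl * fold, 0.95))
          if (fold > 1) {
            tr <- c(tr, list(tibble::tibble(
              chrom = g$chrom, start = starts[j],
              end = starts[j] + span, gene_id = g$gene_id,
              direction = "hyper", compartment = "gene_body")))
          }
        } else {
          lvl <- stats::rbeta(1, sh[1], sh[2])
          regs[[j]] <- island(g$chrom, starts[j], lvl, lvl)
        }
      }
      if (a$hypo_promoter) {
        p0 <- max(if (g$strand == "+") g$tss - 1500L else g$tss + 400L, 0L)
        lvl <- stats::rbeta(1, 8, 2)
        regs <- c(regs, list(island(g$chrom, p0, lvl, lvl / max(fold, 1))))
        if (fold > 1) {
          tr <- c(tr, list(tibble::tibble(
            chrom = g$chrom, start = p0, end = p0 + span,
            gene_id = g$gene_id, direction = "hypo",
            compartment = "promoter")))
        }
      }
      if (a$hypo_intergenic) {
        # 6-10 kb upstream of the span: outside every gene body and
        # promoter (gaps are >= 20 kb), within the 100 kb TSS window
        i0 <- if (g$strand == "+") g$start - 10000L else g$end + 6000L
        if (i0 > 0) {
          lvl <- stats::rbeta(1, 8, 2)
          regs <- c(regs, list(island(g$chrom, i0, lvl, lvl / max(fold, 1))))
          if (fold > 1) {
            tr <- c(tr, list(tibble::tibble(
              chrom = g$chrom, start = i0, end = i0 + span,
              gene_id = g$gene_id, direction = "hypo",
              compartment = "intergenic")))
          }
        }
      }
      pieces[[i]] <- dplyr::bind_rows(regs)
      truth[[i]] <- if (length(tr) > 0) dplyr::bind_rows(tr) else NULL
    }
    all_sites <- dplyr::arrange(dplyr::bind_rows(pieces),
                                .data$chrom, .data$pos)
    list(
      control_sites = dplyr::transmute(all_sites, chrom = .data$chrom,
                                       pos = .data$pos, strand = .data$strand,
                                       meth = .data$meth_control,
                                       total = .data$total_control),
      treated_sites = dplyr::transmute(all_sites, chrom = .data$chrom,
                                       pos = .data$pos, strand = .data$strand,
                                       meth = .data$meth_treated,
                                       total = .data$total_treated),
      truth = dplyr::bind_rows(truth))
  })
}

#' Generate peak sets, differential features and the DE table
#'
#' Enhancer-candidate OCR/H3K27ac peak pairs are placed in gene bodies
#' (Poisson `peak_density` per gene) and in safe intergenic positions;
#' promoter-overlapping OCRs and OCRs without H3K27ac are planted as
#' designed rule violations. Each candidate is present in the pre- and
#' post-treatment condition independently with probability 0.8.
#' Differential OCR/H3K27ac/H3K4me3 features are drawn per gene with
#' class-dependent probabilities so upregulated genes are enriched for
#' gains. The DE table is `de_truth` verbatim (fold changes already
#' clear the thresholds by construction).
#'
#' @param config [study_config()].
#' @param genome Output of [simulate_genome()].
#' @param de_truth Output of [simulate_de_truth()].
#' @return List with per-condition peak tibbles (`ocr_pre`,
#'   `k27ac_pre`, `ocr_post`, `k27ac_post`), `diff_features`, `de`,
#'   and `enhancer_truth` (candidates with `satisfies_rule`,
#'   `in_pre`, `in_post`).
#' @export
simulate_peaks_de <- function(config, genome, de_truth) {
  withr::with_seed(config$seed + 5L, {
    genes <- gene_tss(genome$genes)
    cand <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      # candidates sit in fixed non-overlapping 1.2 kb slots inside the
      # gene body so no planted violation can borrow another
      # candidate's H3K27ac peak, keeping the truth labels exact
      max_slots <- max((g$end - g$start - 1500L) %/% 1200L, 0L)
      n_c <- min(stats::rpois(1, config$peak_density), max_slots)
      if (n_c > 0) {
        for (k in seq_len(n_c)) {
          x <- g$start + 200L + (k - 1L) * 1200L
          cand <- c(cand, list(tibble::tibble(
            chrom = g$chrom, start = x, end = x + 500L,
            kind = "enhancer", has_k27 = TRUE)))
        }
      }
      # planted violations
      if (stats::runif(1) < 0.3) {  # promoter-overlapping OCR
        p0 <- if (g$strand == "+") g$tss - 500L else g$tss - 200L
        cand <- c(cand, list(tibble::tibble(
          chrom = g$chrom, start = max(p0, 0L), end = max(p0, 0L) + 700L,
          kind = "promoter_ocr", has_k27 = TRUE)))
      }
      if (stats::runif(1) < 0.3 && max_slots > n_c + 1) {
        # OCR lacking H3K27ac, in the last slot (>= 1.2 kb clear)
        x <- g$start + 200L + max_slots * 1200L
        cand <- c(cand, list(tibble::tibble(
          chrom = g$chrom, start = x, end = x + 400L,
          kind = "no_k27", has_k27 = FALSE)))
      }
      if (stats::runif(1) < 0.3 && g$start > 16000) {  # intergenic candidate
        x <- g$start - 12000L
        cand <- c(cand, list(tibble::tibble(
          chrom = g$chrom, start = x, end = x + 500L,
          kind = "enhancer", has_k27 = TRUE)))
      }
    }
    cand <- dplyr::bind_rows(cand)
    n <- nrow(cand)
    cand$in_pre <- stats::runif(n) < 0.8
    cand$in_post <- stats::runif(n) < 0.8
    cand$satisfies_rule <- cand$kind == "enhancer"

    mk_peaks <- function(sel, assay) {
      x <- cand[sel, c("chrom", "start", "end"), drop = FALSE]
      dplyr::arrange(
        dplyr::mutate(x, assay = assay, signal = round(stats::runif(nrow(x), 1, 50), 2)),
        .data$chrom, .data$start)
    }
    k27_pad <- function(x) {  # K27ac peak shifted but overlapping the OCR
      dplyr::mutate(x, start = .data$start + 100L, end = .data$end + 300L)
    }
    ocr_pre <- mk_peaks(cand$in_pre, "OCR")
    ocr_post <- mk_peaks(cand$in_post, "OCR")
    k27_pre <- k27_pad(mk_peaks(cand$in_pre & cand$has_k27, "H3K27ac"))
    k27_post <- k27_pad(mk_peaks(cand$in_post & cand$has_k27, "H3K27ac"))

    probs <- list(
      OCR_gain = c(up = 0.45, down = 0.08, null = 0.04),
      H3K27ac_gain = c(up = 0.40, down = 0.05, null = 0.04),
      H3K27ac_loss = c(up = 0.03, down = 0.25, null = 0.04),
      H3K4me3_gain = c(up = 0.30, down = 0.03, null = 0.03),
      H3K4me3_loss = c(up = 0.03, down = 0.20, null = 0.03))
    diff_rows <- list()
    for (nm in names(probs)) {
      assay <- sub("_(gain|loss)$", "", nm)
      dir <- sub("^.*_", "", nm)
      p <- probs[[nm]][de_truth$true_class]
      hit <- stats::runif(nrow(de_truth)) < p
      if (any(hit)) {
        gsel <- genes[match(de_truth$gene_id[hit], genes$gene_id), ]
        diff_rows <- c(diff_rows, list(tibble::tibble(
          chrom = gsel$chrom, start = gsel$start + 200L,
          end = gsel$start + 700L, assay = assay, direction = dir,
          fdr = 10^stats::runif(nrow(gsel), -6, -3),
          gene = gsel$gene_id)))
      }
    }
    diff_features <- dplyr::arrange(dplyr::bind_rows(diff_rows),
                                    .data$chrom, .data$start, .data$assay)

    list(ocr_pre = ocr_pre, k27ac_pre = k27_pre,
         ocr_post = ocr_post, k27ac_post = k27_post,
         diff_features = diff_features,
         de = de_truth[, c("gene_id", "fold_change", "fdr")],
         enhancer_truth = cand)
  })
}

rand_cdr3_nt <- function(n, len_aa = 13) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len_aa * 3, replace = TRUE),
          collapse = "")
  }, "")
}

#' Generate a paired-chain TCR repertoire
#'
#' Builds `n_cells` productive-paired cells realising the configured
#' clonal-group composition exactly: each row of `repertoire_spec`
#' contributes `count` clonotypes of the given size, with member cells
#' spread over the listed clusters of the given treatment arm; all
#' remaining cells are singleton clonotypes. CDR3 nucleotide strings
#' are unique across clonotypes and identical within one. The
#' canonical TRAV11/TRAJ18 alpha pair is assigned to exactly
#' `trav11_traj18_cells` cells; beta V elements follow the major
#' TRBV13-2/TRBV13-1/TRBV1 usage. `n_unproductive` extra cells lack a
#' productive pair and are removed by [filter_productive_paired()].
#'
#' @param config [study_config()].
#' @return List with `cells` (TCR cell tibble, shuffled order) and
#'   `truth` (tibble `cell_id`, `clonotype`).
#' @export
simulate_repertoire <- function(config) {
  withr::with_seed(config$seed + 6L, {
    spec <- config$repertoire_spec
    group_cells <- if (nrow(spec) > 0) {
      sum(rep(spec$size, spec$count))
    } else 0
    n_singletons <- config$n_cells - group_cells
    stopifnot(n_singletons >= 0)

    rows <- list()
    ct <- 0
    for (i in seq_len(nrow(spec))) {
      for (k in seq_len(spec$count[i])) {
        ct <- ct + 1
        cl <- rep_len(spec$clusters[[i]], spec$size[i])
        rows <- c(rows, list(tibble::tibble(
          clonotype = sprintf("truth_ct%04d", ct),
          treatment = spec$treatment[i], cluster = cl)))
      }
    }
    # singleton cells: balance treatment arms around the group cells
    treated_groups <- sum(rep(spec$size, spec$count)[
      rep(spec$treatment, spec$count) == "treated"])
    n_treated_single <- max(round(config$n_cells * 0.47) - treated_groups, 0)
    single_treat <- c(rep("treated", n_treated_single),
                      rep("control", n_singletons - n_treated_single))
    for (i in seq_len(n_singletons)) {
      ct <- ct + 1
      clus <- if (single_treat[i] == "treated") {
        sample(as.character(1:5), 1)
      } else {
        sample(as.character(1:4), 1)
      }
      rows <- c(rows, list(tibble::tibble(
        clonotype = sprintf("truth_ct%04d", ct),
        treatment = single_treat[i], cluster = clus)))
    }
    cells <- dplyr::bind_rows(rows)
    n <- nrow(cells)

    # unique CDR3s per clonotype
    ct_ids <- unique(cells$clonotype)
    repeat {
      a_cdr3 <- rand_cdr3_nt(length(ct_ids))
      b_cdr3 <- rand_cdr3_nt(length(ct_ids))
      if (!anyDuplicated(paste(a_cdr3, b_cdr3))) break
    }
    names(a_cdr3) <- ct_ids; names(b_cdr3) <- ct_ids

    # alpha V/J: exact quota of canonical TRAV11/TRAJ18 assigned per
    # clonotype (so clonotype identity stays consistent)
    canonical <- rep(FALSE, length(ct_ids)); names(canonical) <- ct_ids
    sizes <- table(cells$clonotype)[ct_ids]
    ord <- sample(length(ct_ids))
    cum <- 0
    for (j in ord) {
      if (cum + sizes[j] <= config$trav11_traj18_cells) {
        canonical[j] <- TRUE; cum <- cum + sizes[j]
      }
    }
    b_v_ct <- sample(c("TRBV13-2", "TRBV13-1", "TRBV1", "TRBV29"),
                     length(ct_ids), replace = TRUE,
                     prob = c(196, 35, 18, 94))
    names(b_v_ct) <- ct_ids

    cells <- dplyr::mutate(
      cells,
      a_v = ifelse(canonical[.data$clonotype], "TRAV11", "TRAV12-1"),
      a_j = ifelse(canonical[.data$clonotype], "TRAJ18", "TRAJ12"),
      a_cdr3 = a_cdr3[.data$clonotype], a_productive = TRUE,
      b_v = b_v_ct[.data$clonotype], b_j = "TRBJ2-1",
      b_cdr3 = b_cdr3[.data$clonotype], b_productive = TRUE)

    if (config$n_unproductive > 0) {
      k <- config$n_unproductive
      unp <- tibble::tibble(
        clonotype = NA_character_,
        treatment = sample(c("control", "treated"), k, replace = TRUE),
        cluster = sample(as.character(1:4), k, replace = TRUE),
        a_v = "TRAV11", a_j = "TRAJ18", a_cdr3 = rand_cdr3_nt(k),
        a_productive = sample(c(TRUE, FALSE), k, replace = TRUE),
        b_v = "TRBV13-2", b_j = "TRBJ2-1", b_cdr3 = rand_cdr3_nt(k),
        b_productive = FALSE)
      cells <- dplyr::bind_rows(cells, unp)
    }
    cells <- cells[sample(nrow(cells)), ]
    cells <- dplyr::mutate(cells,
                           cell_id = sprintf("cell%04d", dplyr::row_number()),
                           .before = 1)
    list(cells = dplyr::select(cells, -"clonotype"),
         truth = dplyr::select(cells, "cell_id", "clonotype"))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator under one configuration and returns all
#' pipeline inputs plus ground-truth manifests.
#'
#' @param config [study_config()].
#' @return List: `config`, `genome`, `de_truth`, `assignment`,
#'   `methylome` (control/treated sites + truth), `peaks` (peak sets,
#'   diff features, DE table, enhancer truth), `repertoire`.
#' @export
simulate_study <- function(config = study_config()) {
  genome <- simulate_genome(config)
  de_truth <- simulate_de_truth(config, genome)
  assignment <- simulate_hypo_assignment(config, de_truth)
  methylome <- simulate_methylome(config, genome, de_truth, assignment)
  peaks <- simulate_peaks_de(config, genome, de_truth)
  repertoire <- simulate_repertoire(config)
  list(config = config, genome = genome, de_truth = de_truth,
       assignment = assignment, methylome = methylome, peaks = peaks,
       repertoire = repertoire)
}

#' Write a synthetic study to disk in pipeline dialects
#'
#' Emits the exact file formats the readers consume: a gene-model TSV,
#' Bismark-style CpG reports (1-based positions), BED6+signal peak
#' files, a differential-feature TSV, a DE TSV, a TCR TSV and a JSON
#' truth manifest.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gene_models(study$genome$genes, p("genes.tsv"))
  write_cpg <- function(sites, f) {
    readr::write_tsv(dplyr::transmute(sites, .data$chrom, pos = .data$pos + 1L,
                                      .data$strand, .data$meth,
                                      unmeth = .data$total - .data$meth),
                     p(f), col_names = FALSE)
  }
  write_cpg(study$methylome$control_sites, "control.cov")
  write_cpg(study$methylome$treated_sites, "treated.cov")
  wp <- function(x, f) {
    readr::write_tsv(dplyr::transmute(x, .data$chrom, .data$start, .data$end,
                                      name = ".", score = 0, strand = ".",
                                      signal = .data$signal),
                     p(f), col_names = FALSE)
  }
  wp(study$peaks$ocr_pre, "ocr_pre.bed")
  wp(study$peaks$ocr_post, "ocr_post.bed")
  wp(study$peaks$k27ac_pre, "k27ac_pre.bed")
  wp(study$peaks$k27ac_post, "k27ac_post.bed")
  readr::write_tsv(study$peaks$diff_features, p("diff_features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(study$peaks$de, p("de.tsv"), col_names = FALSE)
  readr::write_tsv(study$repertoire$cells, p("tcr.tsv"), col_names = FALSE)
  truth <- list(dmrs = study$methylome$truth,
                de = study$de_truth[, c("gene_id", "true_class")],
                enhancers = study$peaks$enhancer_truth,
                clonotypes = study$repertoire$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows")
  invisible(dir)
}
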