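# Independent brute-force oracles used across the suite. They share no
# code with the implementation paths they check.

# per-base membership overlap: enumerate every covered (chrom, base)
oracle_overlap <- function(a, b) {
  bases <- function(x) {
    unlist(lapply(seq_len(nrow(x)), function(i) {
      paste(x$chrom[i], seq(x$start[i], x$end[i] - 1L))
    }))
  }
  length(intersect(bases(a), bases(b))) > 0
}

# two-sided Fisher exact P by exhaustive hypergeometric enumeration
# (minimum-likelihood rule, same tie tolerance as fisher.test)
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  support <- lo:hi
  probs <- vapply(support, function(k) {
    exp(lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(m1 + m2, n1))
  }, 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force location classification of one feature against gene
# models: distance checks per gene, no interval machinery
oracle_classify <- function(feature, genes, params = annotation_params()) {
  genes <- gene_tss(genes)
  ov <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)
  body_genes <- genes$gene_id[
    genes$chrom == feature$chrom &
      mapply(ov, genes$start, genes$end, feature$start, feature$end)]
  if (length(body_genes) > 0) {
    return(list(location = "gene_body", linked = sort(body_genes)))
  }
  prom_genes <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != feature$chrom) next
    ps <- if (g$strand == "+") g$tss - params$promoter_upstream_bp
          else g$tss + 1 - params$promoter_downstream_bp
    pe <- if (g$strand == "+") g$tss + params$promoter_downstream_bp
          else g$tss + 1 + params$promoter_upstream_bp
    if (ov(max(ps, 0), pe, feature$start, feature$end)) {
      prom_genes <- c(prom_genes, g$gene_id)
    }
  }
  if (length(prom_genes) > 0) {
    return(list(location = "promoter", linked = sort(unique(prom_genes))))
  }
  win_genes <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != feature$chrom) next
    ws <- max(g$tss - params$gene_window_bp, 0)
    we <- g$tss + params$gene_window_bp + 1
    if (ov(ws, we, feature$start, feature$end)) {
      win_genes <- c(win_genes, g$gene_id)
    }
  }
  list(location = "intergenic", linked = sort(unique(win_genes)))
}

# random interval set on small chromosomes
random_intervals <- function(n, chroms = c("chrA", "chrB"),
                             max_pos = 10000) {
  start <- sample.int(max_pos - 200, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(200, n, replace = TRUE))
}

# CpG site table builder: one row per position
make_sites <- function(chrom, pos, meth, total) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = "+",
                 meth = as.integer(meth), total = as.integer(total))
}

# minimal gene-model builder
make_genes <- function(...) {
  g <- tibble::tibble(...)
  if (!"name" %in% names(g)) g$name <- g$gene_id
  g
}
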