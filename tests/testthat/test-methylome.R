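test_that("CpG report parsing converts coordinates and filters context", {
  path <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t101\t+\t5\t5", "chr1\t201\t-\t0\t10"), path)
  x <- read_cpg_report(path)
  expect_equal(x$pos, c(100L, 200L))
  expect_equal(x$meth, c(5L, 0L))
  expect_equal(x$total, c(10L, 10L))

  writeLines(character(), path)
  expect_equal(nrow(read_cpg_report(path)), 0)

  writeLines("chr1\t101\t+\t-1\t5", path)
  expect_error(read_cpg_report(path), "line 1")

  # context column: non-CpG rows are dropped by default
  writeLines(c("chr1\t101\t+\t5\t5\tCpG", "chr1\t151\t+\t5\t5\tCHH"), path)
  expect_equal(nrow(read_cpg_report(path)), 1)
  expect_equal(nrow(read_cpg_report(path, context = "CHH")), 1)
})

test_that("methylation level is meth/total with NA at zero coverage", {
  x <- methylation_level(make_sites("chr1", c(0, 100, 200, 300),
                                    c(5, 0, 7, 0), c(10, 10, 7, 0)))
  expect_equal(x$level, c(0.5, 0, 1, NA))
  expect_error(methylation_level(make_sites("chr1", 0, 5, 3)), "exceeds")
})

test_that("segmentation forms maximal runs and enforces the CpG minimum", {
  pos6 <- seq(1000, by = 50, length.out = 6)
  ctl <- make_sites("chr1", pos6, 3, 10)
  trt <- make_sites("chr1", pos6, 3, 10)
  cand <- segment_candidates(ctl, trt)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_cpg, 6)
  expect_equal(c(cand$start, cand$end), c(1000, 1251))

  # 4 CpGs only: below the 5-site minimum
  expect_equal(nrow(segment_candidates(ctl[1:4, ], trt[1:4, ])), 0)

  # a 1 kb gap splits two runs of 5
  pos10 <- c(seq(1000, by = 50, length.out = 5),
             seq(3000, by = 50, length.out = 5))
  ctl2 <- make_sites("chr1", pos10, 3, 10)
  expect_equal(nrow(segment_candidates(ctl2, ctl2)), 2)

  # a zero-coverage site widens the gap past max_gap_bp and breaks the run
  pos_wide <- seq(1000, by = 200, length.out = 6)
  ctl3 <- make_sites("chr1", pos_wide, 3, c(10, 10, 10, 0, 10, 10))
  trt3 <- make_sites("chr1", pos_wide, 3, 10)
  expect_equal(nrow(segment_candidates(ctl3, trt3)), 0)
  # with full coverage the same positions form one 6-CpG run
  ctl4 <- make_sites("chr1", pos_wide, 3, 10)
  expect_equal(segment_candidates(ctl4, trt3)$n_cpg, 6)
})

test_that("DMR calling applies fold, P and direction rules on pooled counts", {
  pos <- seq(1000, by = 50, length.out = 6)
  ctl <- make_sites("chr1", pos, 20, 100)
  trt <- make_sites("chr1", pos, 5, 100)
  dmrs <- call_dmrs(ctl, trt)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "hypo")
  expect_equal(dmrs$fold_change, 4)
  expect_equal(dmrs$n_cpg, 6)
  expect_equal(c(dmrs$start, dmrs$end), c(1000, 1251))
  # pooled 2x2 table is (120, 480 | 30, 570): oracle P by exhaustive
  # hypergeometric enumeration
  expect_equal(dmrs$p_value,
               oracle_fisher_two_sided(matrix(c(120, 30, 480, 570), 2)),
               tolerance = 1e-10)
  expect_lt(dmrs$p_value, 1e-10)

  # identical levels: fold 1, no DMR
  expect_equal(nrow(call_dmrs(ctl, ctl)), 0)

  # fold 1.875 (0.30 vs 0.16) fails the 2-fold rule at any P
  trt2 <- make_sites("chr1", pos, 16, 100)
  ctl2 <- make_sites("chr1", pos, 30, 100)
  expect_equal(nrow(call_dmrs(ctl2, trt2)), 0)

  # empty input
  expect_equal(nrow(call_dmrs(ctl[0, ], trt[0, ])), 0)
})

test_that("a zero level in one group passes the fold rule when the other is positive", {
  pos <- seq(1000, by = 50, length.out = 6)
  ctl <- make_sites("chr1", pos, 30, 100)
  trt <- make_sites("chr1", pos, 0, 100)
  dmrs <- call_dmrs(ctl, trt)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$fold_change, Inf)
  expect_equal(dmrs$direction, "hypo")
  # both levels zero: no call
  z <- make_sites("chr1", pos, 0, 100)
  expect_equal(nrow(call_dmrs(z, z)), 0)
})

test_that("replicate rows at one position are pooled by summing", {
  pos <- seq(1000, by = 50, length.out = 5)
  rep1 <- make_sites("chr1", pos, 10, 50)
  rep2 <- make_sites("chr1", pos, 10, 50)
  ctl <- dplyr::bind_rows(rep1, rep2)   # pooled: 20/100 per site
  trt <- make_sites("chr1", pos, 5, 100)
  dmrs <- call_dmrs(ctl, trt)
  expect_equal(dmrs$level_control, 0.2)
  expect_equal(dmrs$fold_change, 4)
})

test_that("merging joins abutting same-direction DMRs and is idempotent", {
  # two adjacent 5-CpG hypo runs separated by > max_gap so they are
  # distinct candidates, with nothing tested in between
  pos_a <- seq(1000, by = 50, length.out = 5)
  pos_b <- seq(1800, by = 50, length.out = 5)
  ctl <- make_sites("chr1", c(pos_a, pos_b), 40, 100)
  trt <- make_sites("chr1", c(pos_a, pos_b), 10, 100)
  dmrs <- call_dmrs(ctl, trt)
  expect_equal(nrow(dmrs), 2)
  merged <- merge_adjacent_dmrs(dmrs, ctl, trt)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_cpg, 10)
  expect_equal(merged$direction, "hypo")
  expect_equal(c(merged$start, merged$end), c(1000, 2001))
  # idempotence
  expect_equal(merge_adjacent_dmrs(merged, ctl, trt), merged)
})

test_that("merging respects direction and intervening failed candidates", {
  pos_a <- seq(1000, by = 50, length.out = 5)
  pos_b <- seq(1800, by = 50, length.out = 5)
  # opposite directions: no merge
  ctl <- make_sites("chr1", c(pos_a, pos_b), c(rep(40, 5), rep(10, 5)), 100)
  trt <- make_sites("chr1", c(pos_a, pos_b), c(rep(10, 5), rep(40, 5)), 100)
  dmrs <- call_dmrs(ctl, trt)
  expect_equal(sort(dmrs$direction), c("hyper", "hypo"))
  expect_equal(nrow(merge_adjacent_dmrs(dmrs, ctl, trt)), 2)

  # an equal-level (failed) candidate between two hypo DMRs blocks the merge
  pos_a <- seq(1000, by = 50, length.out = 5)
  pos_mid <- seq(1600, by = 50, length.out = 5)
  pos_b <- seq(2200, by = 50, length.out = 5)
  ctl2 <- make_sites("chr1", c(pos_a, pos_mid, pos_b),
                     c(rep(40, 5), rep(25, 5), rep(40, 5)), 100)
  trt2 <- make_sites("chr1", c(pos_a, pos_mid, pos_b),
                     c(rep(10, 5), rep(25, 5), rep(10, 5)), 100)
  dmrs2 <- call_dmrs(ctl2, trt2)
  expect_equal(nrow(dmrs2), 2)
  expect_equal(nrow(merge_adjacent_dmrs(dmrs2, ctl2, trt2)), 2)
})

test_that("BH q-values are monotone in sorted P order and at least P", {
  withr::with_seed(13, {
    # 40 candidate islands with random levels
    pieces_c <- list(); pieces_t <- list()
    for (k in 1:40) {
      pos <- seq(k * 5000, by = 50, length.out = 6)
      lc <- runif(1, 0.1, 0.9)
      lt <- runif(1, 0.1, 0.9)
      pieces_c[[k]] <- make_sites("chr1", pos, rbinom(6, 60, lc), 60)
      pieces_t[[k]] <- make_sites("chr1", pos, rbinom(6, 60, lt), 60)
    }
    ctl <- dplyr::bind_rows(pieces_c); trt <- dplyr::bind_rows(pieces_t)
    params <- dmr_params(min_fold = 1, alpha = 1)  # keep all candidates
    dmrs <- call_dmrs(ctl, trt, params)
    expect_true(all(dmrs$q_value >= dmrs$p_value))
    ord <- order(dmrs$p_value)
    expect_true(all(diff(dmrs$q_value[ord]) >= -1e-12))
    # q matches stats::p.adjust on the same P vector
    expect_equal(sort(dmrs$q_value),
                 sort(stats::p.adjust(dmrs$p_value, "BH")))
  })
})

test_that("calling is invariant to site order and chromosome naming", {
  withr::with_seed(5, {
    pos <- seq(1000, by = 50, length.out = 8)
    ctl <- make_sites("chr1", pos, rbinom(8, 80, 0.7), 80)
    trt <- make_sites("chr1", pos, rbinom(8, 80, 0.2), 80)
    base <- call_dmrs(ctl, trt)
    perm <- sample(8)
    shuf <- call_dmrs(ctl[perm, ], trt[rev(perm), ])
    expect_equal(base, shuf)
    ren <- function(x) dplyr::mutate(x, chrom = "scaffold_77")
    renamed <- call_dmrs(ren(ctl), ren(trt))
    expect_equal(dplyr::select(base, -"chrom"),
                 dplyr::select(renamed, -"chrom"))
  })
})

test_that("under the null the Fisher rejection rate stays at or below nominal", {
  withr::with_seed(99, {
    n_cand <- 2000
    lvl <- 0.5
    pieces_c <- vector("list", n_cand); pieces_t <- vector("list", n_cand)
    for (k in seq_len(n_cand)) {
      pos <- seq(k * 3000, by = 50, length.out = 5)
      pieces_c[[k]] <- make_sites("chr1", pos, rbinom(5, 30, lvl), 30)
      pieces_t[[k]] <- make_sites("chr1", pos, rbinom(5, 30, lvl), 30)
    }
    ctl <- dplyr::bind_rows(pieces_c); trt <- dplyr::bind_rows(pieces_t)
    params <- dmr_params(min_fold = 1, alpha = 1)
    dmrs <- call_dmrs(ctl, trt, params)
    expect_equal(nrow(dmrs), n_cand)
    rate <- mean(dmrs$p_value <= 0.05)
    se <- sqrt(0.05 * 0.95 / n_cand)
    expect_lte(rate, 0.05 + 3 * se)
  })
})

test_that("DMR annotation places regions in the right compartment", {
  genes <- make_genes(gene_id = "g1", chrom = "chr1", start = 100000L,
                      end = 120000L, strand = "+")
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(105000L, 98500L, 180000L),
                         end = c(106000L, 99000L, 181000L),
                         direction = "hypo")
  ann <- annotate_dmrs(dmrs, genes)
  expect_equal(ann$location, c("gene_body", "promoter", "intergenic"))
  # 80 kb from the TSS: inside the 100 kb window
  expect_equal(ann$linked_genes[[3]], "g1")
})
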