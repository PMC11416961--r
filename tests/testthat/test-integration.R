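# mark matrix with only gene-body hypo-methylation set, built directly
# from a truth assignment (used by the recovery tests)
matrix_from_assignment <- function(assignment) {
  mm <- tibble::tibble(gene_id = assignment$gene_id,
                       hypo_gene_body = assignment$hypo_body)
  for (mk in setdiff(epimark:::mark_names, "hypo_gene_body")) {
    mm[[mk]] <- FALSE
  }
  mm$de_class <- dplyr::recode(assignment$true_class, null = "unchanged")
  mm
}

test_that("chi-square 2x2 handles the no-association and error cases", {
  res <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$p_one_sided, 0.5)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_2x2(matrix(c(1, 2, 3), nrow = 1)), "2x2")
  g <- glance(chi_square_2x2(matrix(c(9, 1, 2, 8), 2), sided = "two"))
  expect_equal(g$p.value, g$p_two_sided)
})

test_that("one-sided chi-square halves toward the observed direction", {
  # enrichment of the first cell: one-sided = two-sided / 2
  pos <- chi_square_2x2(matrix(c(20, 5, 10, 15), 2))
  expect_true(pos$direction_positive)
  expect_equal(pos$p_one_sided, pos$p_two_sided / 2)
  # depletion: one-sided = 1 - two-sided / 2
  neg <- chi_square_2x2(matrix(c(5, 20, 15, 10), 2))
  expect_false(neg$direction_positive)
  expect_equal(neg$p_one_sided, 1 - neg$p_two_sided / 2)
})

test_that("Fisher exact P matches exhaustive enumeration up to N = 60", {
  # the worked diagonal case: 2 / choose(10, 5)
  res <- fisher_2x2(matrix(c(0, 5, 5, 0), 2))
  expect_equal(res$p_two_sided, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_2x2(matrix(c(1, 1, 1, 1), 2))$p_two_sided, 1)
  withr::with_seed(21, {
    for (rep in 1:60) {
      n <- sample(4:60, 1)
      cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
      tab <- matrix(cells, 2)
      expect_equal(fisher_2x2(tab)$p_two_sided,
                   oracle_fisher_two_sided(tab), tolerance = 1e-10)
    }
  })
})

test_that("one-sided chi-square agrees with a permutation mid-p null on well-conditioned tables", {
  # tables with all expected counts >= 14; for such tables the halved
  # chi-square approximates the fixed-margin permutation null under the
  # mid-p tie convention
  tables <- list(matrix(c(45, 105, 30, 120), 2, byrow = TRUE),
                 matrix(c(60, 90, 45, 105), 2, byrow = TRUE),
                 matrix(c(90, 60, 75, 75), 2, byrow = TRUE))
  withr::with_seed(1234, {
    for (tab in tables) {
      p_chi <- chi_square_2x2(tab)$p_one_sided
      B <- 200000
      sims <- stats::r2dtable(B, rowSums(tab), colSums(tab))
      n11 <- vapply(sims, function(m) m[1, 1], 0)
      p_perm <- mean(n11 > tab[1, 1]) + 0.5 * mean(n11 == tab[1, 1])
      se <- sqrt(p_perm * (1 - p_perm) / B)
      expect_lt(abs(p_chi - p_perm), 3 * se)
    }
  })
})

test_that("odds ratios report Inf on zero cells with a Haldane estimate alongside", {
  res <- chi_square_2x2(matrix(c(10, 0, 152, 76), 2))
  expect_equal(res$odds_ratio, Inf)
  expect_equal(res$odds_ratio_haldane,
               (10.5 * 76.5) / (152.5 * 0.5))
  td <- tidy(res)
  expect_equal(td$odds_ratio, Inf)
})

test_that("the mark matrix matches a brute-force per-gene re-derivation", {
  cfg <- study_config(seed = 31, n_genes = 60, n_up = 15, n_down = 8,
                      coverage_mean = 60)
  st <- simulate_study(cfg)
  res <- run_pipeline(st)
  mm <- res$mark_matrix
  expect_setequal(mm$gene_id, st$genome$genes$gene_id)

  # independent join: per gene, scan each upstream table directly
  dmrs <- res$dmrs
  for (g in sample(mm$gene_id, 20)) {
    row <- mm[mm$gene_id == g, ]
    in_dmr <- function(dir, loc) {
      any(vapply(seq_len(nrow(dmrs)), function(i) {
        dmrs$direction[i] == dir && dmrs$location[i] == loc &&
          g %in% dmrs$linked_genes[[i]]
      }, TRUE))
    }
    expect_equal(row$hypo_gene_body, in_dmr("hypo", "gene_body"))
    expect_equal(row$hypo_promoter, in_dmr("hypo", "promoter"))
    expect_equal(row$hypo_intergenic, in_dmr("hypo", "intergenic"))
    expect_equal(row$hyper_gene_body, in_dmr("hyper", "gene_body"))
    df <- st$peaks$diff_features
    expect_equal(row$diff_ocr_gain,
                 any(df$gene == g & df$assay == "OCR" & df$direction == "gain"))
    expect_equal(row$k27ac_loss,
                 any(df$gene == g & df$assay == "H3K27ac" &
                       df$direction == "loss"))
    expect_equal(row$enhancer_post,
                 any(vapply(res$enhancers_post$linked_genes,
                            function(l) g %in% l, TRUE)))
    expect_equal(row$hypo_enhancer_50kb, g %in% res$hypo_links$gene_id)
  }
  # a gene id outside the universe is rejected
  expect_error(
    build_mark_matrix(mm$gene_id[1:5],
                      diff_features = tibble::tibble(
                        assay = "OCR", direction = "gain", gene = "alien")),
    "outside the universe")
})

test_that("association report reproduces hand-computed proportions", {
  # 162 up genes of which 55 marked; 76 down of which 6 marked
  mm <- matrix_from_assignment(tibble::tibble(
    gene_id = sprintf("g%d", 1:238),
    hypo_body = c(rep(TRUE, 55), rep(FALSE, 107), rep(TRUE, 6), rep(FALSE, 70)),
    true_class = c(rep("up", 162), rep("down", 76))))
  rep <- association_report(mm, "hypo_gene_body")
  expect_equal(rep$pct_up, 33.95)
  expect_equal(rep$pct_down, 7.89)
  expect_equal(rep$up_count, 55)
  expect_lt(rep$p_one_sided, 1e-4)
  # all-false mark: zero margin reported as NA, not an error
  mm$hypo_gene_body <- FALSE
  rep0 <- association_report(mm, "hypo_gene_body")
  expect_true(is.na(rep0$p_one_sided))
  expect_equal(rep0$pct_up, 0)
})

test_that("epigenetic groups partition the gene set", {
  mk_row <- function(hypo, ocr, k27) {
    mm <- matrix_from_assignment(tibble::tibble(
      gene_id = "g", hypo_body = hypo, true_class = "up"))
    mm$diff_ocr_gain <- ocr
    mm$k27ac_gain <- k27
    epigenetic_group(mm)$epi_group
  }
  expect_equal(mk_row(TRUE, TRUE, TRUE), "Group1")
  expect_equal(mk_row(TRUE, FALSE, TRUE), "Group2")
  expect_equal(mk_row(TRUE, TRUE, FALSE), "Group3")
  expect_equal(mk_row(TRUE, FALSE, FALSE), "Group4")
  expect_equal(mk_row(FALSE, TRUE, TRUE), "ungrouped")

  withr::with_seed(8, {
    mm <- matrix_from_assignment(tibble::tibble(
      gene_id = sprintf("g%d", 1:200),
      hypo_body = runif(200) < 0.5,
      true_class = sample(c("up", "down", "null"), 200, replace = TRUE)))
    mm$diff_ocr_gain <- runif(200) < 0.3
    mm$k27ac_gain <- runif(200) < 0.3
    mm$hypo_promoter <- runif(200) < 0.2
    grp <- epigenetic_group(mm)
    expect_equal(nrow(grp), 200)
    expect_equal(sum(table(grp$epi_group)), 200)
    # every gene gets exactly one of the five labels
    expect_true(all(grp$epi_group %in%
                      c("Group1", "Group2", "Group3", "Group4", "ungrouped")))
  })
})

test_that("mark tallies and burden histograms are column sums by class", {
  mm <- matrix_from_assignment(tibble::tibble(
    gene_id = c("a", "b", "c"),
    hypo_body = c(TRUE, FALSE, TRUE),
    true_class = c("up", "up", "down")))
  tally <- mark_weight_tally(mm)
  expect_equal(tally$up[tally$mark == "hypo_gene_body"], 1)
  expect_equal(tally$down[tally$mark == "hypo_gene_body"], 1)
  expect_true(all(tally$up[tally$mark != "hypo_gene_body"] == 0))

  mm$diff_ocr_gain <- c(TRUE, FALSE, FALSE)
  mm$k27ac_gain <- c(TRUE, FALSE, FALSE)
  mm$k4me3_gain <- c(TRUE, FALSE, FALSE)
  burden <- modification_burden(mm)
  expect_equal(burden$per_gene$burden, c(4, 0, 1))
  pct_by_class <- tapply(burden$histogram$pct, burden$histogram$de_class, sum)
  expect_true(all(abs(pct_by_class - 100) < 1e-9))
})

test_that("the estimated mark-expression odds ratio recovers theta = 6", {
  hits <- 0
  for (r in 1:100) {
    cfg <- study_config(seed = 1000 + r, theta = 6)
    genome <- list(genes = tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(cfg$n_genes))))
    de <- tibble::tibble(gene_id = genome$genes$gene_id)
    cls <- rep("null", cfg$n_genes)
    cls[seq_len(cfg$n_up)] <- "up"
    cls[cfg$n_up + seq_len(cfg$n_down)] <- "down"
    de$true_class <- cls
    asg <- simulate_hypo_assignment(cfg, de)
    mm <- matrix_from_assignment(asg)
    rep <- association_report(mm, "hypo_gene_body")
    tab <- matrix(c(rep$up_count, rep$up_total - rep$up_count,
                    rep$down_count, rep$down_total - rep$down_count),
                  2, byrow = TRUE)
    ci <- stats::fisher.test(tab)$conf.int
    if (ci[1] <= 6 && 6 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("the one-sided test holds its size at theta = 1", {
  rejections <- 0
  for (r in 1:1000) {
    cfg <- study_config(seed = 20000 + r, theta = 1)
    de <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(cfg$n_genes)))
    cls <- rep("null", cfg$n_genes)
    cls[seq_len(cfg$n_up)] <- "up"
    cls[cfg$n_up + seq_len(cfg$n_down)] <- "down"
    de$true_class <- cls
    asg <- simulate_hypo_assignment(cfg, de)
    mm <- matrix_from_assignment(asg)
    rep <- association_report(mm, "hypo_gene_body")
    if (!is.na(rep$p_one_sided) && rep$p_one_sided <= 0.05) {
      rejections <- rejections + 1
    }
  }
  rate <- rejections / 1000
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
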