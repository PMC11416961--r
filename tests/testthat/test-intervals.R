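test_that("interval overlap follows the half-open convention", {
  iv <- function(chrom, start, end) tibble::tibble(chrom = chrom,
                                                   start = start, end = end)
  expect_true(intervals_overlap(iv("chr1", 100, 200), iv("chr1", 199, 300)))
  expect_false(intervals_overlap(iv("chr1", 100, 200), iv("chr1", 200, 300)))
  expect_false(intervals_overlap(iv("chr1", 100, 200), iv("chr2", 100, 200)))
  # symmetry
  expect_equal(intervals_overlap(iv("chr1", 100, 200), iv("chr1", 150, 400)),
               intervals_overlap(iv("chr1", 150, 400), iv("chr1", 100, 200)))
})

test_that("promoters are 2 kb upstream by default, strand-mirrored, clipped", {
  genes <- make_genes(
    gene_id = c("gp", "gm", "gclip"),
    chrom = "chr1",
    start = c(10000L, 5000L, 500L),
    end = c(20000L, 9999L, 4000L),
    strand = c("+", "-", "+"))
  pr <- promoters_of(genes)
  expect_equal(pr$start[pr$gene_id == "gp"], 8000)
  expect_equal(pr$end[pr$gene_id == "gp"], 10000)
  # minus strand: tss = end - 1 = 9998; promoter upstream in genomic
  # coordinates is [9999, 11999)
  expect_equal(pr$start[pr$gene_id == "gm"], 9999)
  expect_equal(pr$end[pr$gene_id == "gm"], 11999)
  expect_equal(pr$start[pr$gene_id == "gclip"], 0)
  expect_equal(pr$end[pr$gene_id == "gclip"], 500)
  # symmetric reading via promoter_downstream_bp
  pr2 <- promoters_of(genes[1, ], annotation_params(promoter_downstream_bp = 2000))
  expect_equal(c(pr2$start, pr2$end), c(8000, 12000))
})

test_that("tss_window is symmetric, strand-independent and clipped", {
  genes <- make_genes(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(200000L, 50000L), end = c(210000L, 60000L),
                      strand = c("+", "+"))
  w <- tss_window(genes, 100000)
  expect_equal(c(w$start[1], w$end[1]), c(100000, 300001))
  expect_equal(c(w$start[2], w$end[2]), c(0, 150001))
  w0 <- tss_window(genes[1, ], 0)
  expect_equal(c(w0$start, w0$end), c(200000, 200001))
  # strand does not matter for a fixed tss position
  gm <- make_genes(gene_id = "m", chrom = "chr1", start = 100000L,
                   end = 200001L, strand = "-")
  expect_equal(tss_window(gm, 5000)$start, 195000)
})

test_that("classify_location applies gene_body > promoter > intergenic", {
  genes <- make_genes(gene_id = "g1", chrom = "chr1", start = 100000L,
                      end = 110000L, strand = "+")
  feats <- tibble::tibble(
    chrom = "chr1",
    start = c(101000L, 99000L, 170000L, 300000L),
    end = c(102000L, 99500L, 171000L, 301000L))
  cl <- classify_location(feats, genes)
  expect_equal(cl$location, c("gene_body", "promoter", "intergenic",
                              "intergenic"))
  expect_equal(cl$linked_genes[[1]], "g1")
  expect_equal(cl$linked_genes[[2]], "g1")
  # 60-70 kb downstream of the TSS: inside the 100 kb window
  expect_equal(cl$linked_genes[[3]], "g1")
  # 200 kb away: outside the window, linked to nothing
  expect_equal(cl$linked_genes[[4]], character())
})

test_that("classification matches the brute-force oracle on random genomes", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n_genes <- sample(3:6, 1)
      gstart <- sort(sample.int(8000, n_genes))
      genes <- make_genes(
        gene_id = sprintf("g%d", seq_len(n_genes)),
        chrom = sample(c("chrA", "chrB"), n_genes, replace = TRUE),
        start = gstart, end = gstart + sample(100:800, n_genes),
        strand = sample(c("+", "-"), n_genes, replace = TRUE))
      params <- annotation_params(promoter_upstream_bp = 300,
                                  gene_window_bp = 1500)
      feats <- random_intervals(15)
      cl <- classify_location(feats, genes, params)
      for (i in seq_len(nrow(feats))) {
        expected <- oracle_classify(feats[i, ], genes, params)
        expect_equal(cl$location[i], expected$location)
        expect_equal(sort(cl$linked_genes[[i]]), expected$linked)
      }
    }
  })
})

test_that("overlap detection matches the per-base oracle on random sets", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      a <- random_intervals(8)
      b <- random_intervals(8)
      got <- overlaps_any <- epimark:::overlaps_any(a, b)
      for (i in seq_len(nrow(a))) {
        expect_equal(got[i], oracle_overlap(a[i, ], b))
      }
    }
  })
})

test_that("classification is invariant to gene and feature ordering", {
  withr::with_seed(11, {
    gstart <- sort(sample.int(8000, 5))
    genes <- make_genes(gene_id = sprintf("g%d", 1:5), chrom = "chrA",
                        start = gstart, end = gstart + 300,
                        strand = sample(c("+", "-"), 5, replace = TRUE))
    feats <- random_intervals(10, chroms = "chrA")
    base <- classify_location(feats, genes)
    perm <- sample(5)
    shuffled <- classify_location(feats, genes[perm, ])
    expect_equal(base$location, shuffled$location)
    expect_equal(lapply(base$linked_genes, sort),
                 lapply(shuffled$linked_genes, sort))
  })
})

test_that("BED round-trips and rejects malformed records", {
  path <- withr::local_tempfile(fileext = ".bed")
  x <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0L, 500L),
                      end = c(100L, 900L), extra1 = c("peak1", "peak2"))
  write_bed(x, path)
  expect_equal(read_bed(path), x)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t50", bad)
  expect_error(read_bed(bad), "end <= start")
  writeLines("chr1\t100", bad)
  expect_error(read_bed(bad), "line 1")
  writeLines(c("chr1\t0\t10", "chr1\tx\t20"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("gene model I/O round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  genes <- make_genes(gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
                      start = c(100L, 5000L), end = c(1000L, 9000L),
                      strand = c("+", "-"))
  write_gene_models(genes, path)
  expect_equal(read_gene_models(path), genes)
})
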