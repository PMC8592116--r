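test_that("the LD interval follows the r2 >= 0.2 / 500-kb rule", {
  ld <- data.frame(pos = c(101700000, 102300000, 102800000),
                   r2 = c(0.35, 0.21, 0.9))
  expect_equal(define_locus_interval(102000000, ld),
               c(start = 101700000L, end = 102300000L))

  ## a high-LD SNP beyond the cap never qualifies: that side collapses
  ld2 <- data.frame(pos = c(101400000, 102300000), r2 = c(0.9, 0.3))
  expect_equal(define_locus_interval(102000000, ld2),
               c(start = 102000000L, end = 102300000L))

  expect_warning(
    iv <- define_locus_interval(102000000, data.frame(pos = integer(),
                                                      r2 = numeric())),
    "degenerate")
  expect_equal(iv, c(start = 102000000L, end = 102000000L))
  expect_error(define_locus_interval(1e6, data.frame(pos = 1e6, r2 = 1.4)),
               "r2")
})

test_that("interval construction matches a brute-force scan and is monotone", {
  set.seed(71)
  for (i in 1:50) {
    index <- 50000000L
    n <- sample(0:40, 1)
    ld <- data.frame(pos = index + sample(-700000:700000, n),
                     r2 = round(runif(n), 3))
    r2_min <- sample(c(0.1, 0.2, 0.5), 1)
    if (n == 0) {
      expect_warning(iv <- define_locus_interval(index, ld, r2_min))
    } else {
      iv <- suppressWarnings(define_locus_interval(index, ld, r2_min))
    }
    expect_equal(iv, interval_brute(index, ld, r2_min))

    ## raising r2_min never widens; raising max_dist never narrows
    iv_hi <- suppressWarnings(
      define_locus_interval(index, ld, r2_min + 0.2))
    expect_gte(iv_hi[["start"]], iv[["start"]])
    expect_lte(iv_hi[["end"]], iv[["end"]])
    iv_wide <- suppressWarnings(
      define_locus_interval(index, ld, r2_min, max_dist = 700000))
    expect_lte(iv_wide[["start"]], iv[["start"]])
    expect_gte(iv_wide[["end"]], iv[["end"]])
  }
})

test_that("candidate genes are those overlapping the 3-Mb window, by start", {
  index <- 102000000L
  ann <- gene_models(
    gene_id = c("edge_out", "edge_in", "inside"),
    chrom = "11",
    start = c(index - 1600000, index - 1501000, index - 100000),
    end = c(index - 1550000, index - 1499000, index - 50000))
  locus <- suppressWarnings(
    locus_definition("11p13", "rs2592555", "11", index))
  expect_equal(candidate_genes(locus, ann), c("edge_in", "inside"))

  ## published 11p13 top three all sit in the window
  locus2 <- suppressWarnings(
    locus_definition("11p13", "rs2592555", "11", index,
                     annotation = demo_annotation()))
  expect_true(all(c("PRR5L", "TRAF6", "COMMD9") %in%
                    locus2$candidate_genes))
  expect_false("FARAWAY" %in% locus2$candidate_genes)

  expect_warning(
    none <- candidate_genes(
      suppressWarnings(locus_definition("x", "rs1", "7", index)), ann),
    "chromosome")
  expect_equal(none, character(0))
})

test_that("nearest genes use gene-body edge distance, per direction", {
  ann <- demo_annotation()
  expect_equal(nearest_genes(102000000, ann, chrom = "11"), "PRR5L")
  ann2 <- gene_models(gene_id = c("A", "B", "C"), chrom = "1",
                      start = c(100, 30000, 40000),
                      end = c(5000, 32000, 42000))
  expect_equal(sort(nearest_genes(10000, ann2)), c("A", "B"))
  ## equal-distance tie on one side returns both, with a message
  ann3 <- gene_models(gene_id = c("L1", "L2", "R"), chrom = "1",
                      start = c(100, 200, 9000), end = c(1000, 1000, 9500))
  expect_message(tie <- nearest_genes(2000, ann3), "tie")
  expect_setequal(tie, c("L1", "L2", "R"))
})

test_that("randomized geometry agrees with brute force end to end", {
  set.seed(72)
  for (i in 1:40) {
    index <- sample(3000000:9000000, 1)
    n_genes <- sample(1:15, 1)
    starts <- sample((index - 2000000):(index + 2000000), n_genes)
    ann <- gene_models(gene_id = paste0("g", seq_len(n_genes)), chrom = "2",
                       start = starts, end = starts + sample(500:200000,
                                                             n_genes,
                                                             replace = TRUE))
    locus <- suppressWarnings(
      locus_definition("rand", "rsX", "2", index, annotation = ann))
    expect_equal(locus$candidate_genes,
                 candidates_brute(locus$gene_window, "2", ann))
    expect_equal(sort(suppressMessages(nearest_genes(index, ann))),
                 sort(suppressMessages(nearest_brute(index, ann))))
    ## nearest genes live in the (non-degenerate) candidate window
    expect_true(all(locus$nearest_genes %in% locus$candidate_genes))
  }
})

test_that("secondary signals merge into one locus by interval union", {
  ld1 <- data.frame(pos = c(1000000, 1200000), r2 = c(0.5, 0.4))
  ld2 <- data.frame(pos = c(1500000, 1700000), r2 = c(0.6, 0.3))
  locus <- locus_definition(
    "2q12.1", "rs6419573", "2", 1100000, ld = ld1,
    secondary = list(list(snp = "rs3917265", pos = 1600000, ld = ld2)))
  expect_equal(locus$interval, c(start = 1000000L, end = 1700000L))
  expect_equal(locus$secondary_index_snps, "rs3917265")
  expect_equal(locus$gene_window[["end"]], 1600000L + 1500000L)
})

test_that("BED annotation is read through rtracklayer with 1-based output", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tGENEA\t0\t+",
               "chr1\t5000\t6000\tGENEB\t0\t-"), path)
  ann <- read_gene_annotation(path)
  expect_equal(ann$gene_id, c("GENEA", "GENEB"))
  expect_equal(ann$start, c(1000L, 5001L))  # BED 0-based converted
  expect_equal(ann$end, c(2000L, 6000L))
  expect_equal(ann$tss, c(1000L, 6000L))    # strand-aware TSS
})
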