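test_that("component scores multiply weight, magnitude, specificity, 1/sqrt(k)", {
  r <- evidence_records(ev_row(magnitude = 0.9, n_sig = 100L))
  ## 20 * 0.9 * 1/(1+2) / sqrt(4) = 3
  expect_equal(component_score(r, k = 4)$value, 3)
  expect_equal(component_score(evidence_records(ev_row(magnitude = 0)))$value,
               0)
  ## value never exceeds the class weight
  set.seed(5)
  for (i in 1:20) {
    r <- evidence_records(ev_row(magnitude = runif(1),
                                 n_sig = sample(1:10000, 1),
                                 evidence_class = sample(
                                   c("stat_full", "overlap", "prediction"),
                                   1)))
    cs <- component_score(r, k = sample(1:5, 1))
    expect_lte(cs$value, cs$weight)
    expect_gte(cs$value, 0)
  }
})

test_that("class dominance ratios are exactly 10 and 2 at equal factors", {
  mk <- function(cls) evidence_records(
    ev_row(evidence_class = cls, magnitude = 0.8, n_sig = 7L))
  v <- vapply(c("stat_full", "overlap", "prediction"),
              function(cl) component_score(mk(cl), k = 2)$value, numeric(1))
  expect_identical(v[["stat_full"]] / v[["overlap"]], 10)
  expect_identical(v[["overlap"]] / v[["prediction"]], 2)
})

test_that("heterogeneity multiplier is sqrt of the mean unique-count", {
  expect_equal(heterogeneity_multiplier(
    data.frame(study_type = letters[1:4], study_id = LETTERS[1:4])), 2)
  expect_equal(heterogeneity_multiplier(
    data.frame(study_type = "a", study_id = "A")), 1)
  expect_equal(heterogeneity_multiplier(
    data.frame(study_type = rep(c("a", "b"), 4),
               study_id = paste0("S", 1:8))), sqrt(5))
  expect_equal(heterogeneity_multiplier(NULL), 1)
  ## enumerated grid
  for (ut in 1:4) for (ui in ut:5) {
    recs <- data.frame(study_type = rep_len(paste0("t", 1:ut), ui),
                       study_id = paste0("s", 1:ui))
    expect_equal(heterogeneity_multiplier(recs), sqrt((ut + ui) / 2))
  }
})

test_that("target totals sum components and apply the heterogeneity term", {
  empty <- evidence_records(ev_row())[0, ]
  expect_equal(score_target("GENE1", empty)$total, 0)

  single <- evidence_records(ev_row(magnitude = 1))
  expect_equal(score_target("GENE1", single)$total, 20)

  three <- ev_tbl(
    ev_row(study_id = "s1", study_type = "coloc",
           evidence_class = "stat_full", magnitude = 0.8),
    ev_row(study_id = "s2", study_type = "enhancer_loop",
           evidence_class = "overlap", magnitude = 1),
    ev_row(study_id = "s3", study_type = "regulatory_pred",
           evidence_class = "prediction", magnitude = 0.5))
  ts <- score_target("GENE1", three)
  expect_equal(ts$raw_sum, 18.5)
  expect_equal(ts$heterogeneity_multiplier, sqrt(3))
  expect_equal(ts$total, 18.5 * sqrt(3), tolerance = 1e-12)
  expect_equal(round(ts$total, 3), 32.043)
  expect_equal(ts$n_unique_study_types, 3)
  expect_equal(ts$n_unique_study_ids, 3)
})

test_that("SNP records propagate to their linked gene; same-study records share k", {
  recs <- ev_tbl(
    ev_row(target_id = "GENE1", study_id = "s1", magnitude = 1),
    ev_row(target_type = "snp", target_id = "rs1", linked_gene = "GENE1",
           study_id = "s1", study_type = "mqtl", evidence_class = "overlap",
           magnitude = 1))
  ts <- score_target("GENE1", recs)
  ## both records from study s1: the weaker one is damped by sqrt(2);
  ## het sqrt((2 types + 1 study) / 2)
  expect_equal(ts$raw_sum, 20 + 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(ts$heterogeneity_multiplier, sqrt(3 / 2))
  ## the unlinked SNP record alone scores the SNP target
  expect_equal(score_target("rs1", recs, target_type = "snp")$total, 2)
})

test_that("adding evidence never lowers a total; more n_sig never raises it", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    base <- do.call(rbind, lapply(seq_len(n), function(j) {
      ev_row(study_id = sample(paste0("s", 1:3), 1),
             study_type = sample(c("eqtl", "coloc", "dge"), 1),
             evidence_class = sample(c("stat_full", "overlap",
                                       "prediction"), 1),
             magnitude = runif(1), n_sig = sample(1:1000, 1))
    }))
    t0 <- score_target("GENE1", evidence_records(base))$total
    extra <- ev_row(study_id = sample(paste0("s", 1:4), 1),
                    study_type = "pqtl", evidence_class = "overlap",
                    magnitude = runif(1, 0.01, 1))
    t1 <- score_target("GENE1", evidence_records(rbind(base, extra)))$total
    expect_gte(t1, t0)

    harder <- base
    harder$n_sig <- harder$n_sig * 10L
    t2 <- score_target("GENE1", evidence_records(harder))$total
    expect_lte(t2, t0)
  }
})

test_that("locus scoring covers all candidates, applies membership rules", {
  ann <- gene_models(gene_id = c("A", "B"), chrom = "1",
                     start = c(990000, 1200000), end = c(1010000, 1220000))
  ld <- data.frame(snp_id = c("rsIDX", "rsIN", "rsOUT"), chrom = "1",
                   pos = c(1000000, 1050000, 1900000),
                   r2 = c(1, 0.5, 0.9))
  locus <- locus_definition("L1", "rsIDX", "1", 1000000, ld = ld,
                            annotation = ann)
  ev <- ev_tbl(
    ev_row(target_id = "A", magnitude = 0.9),
    ev_row(target_type = "snp", target_id = "rsIN", study_id = "s2",
           evidence_class = "overlap", magnitude = 1),
    ev_row(target_type = "snp", target_id = "rsOUT", study_id = "s3",
           evidence_class = "overlap", magnitude = 1))
  expect_warning(scores <- score_locus(locus, ev, snp_positions = ld),
                 "outside the LD interval")
  expect_setequal(scores$genes$target_id, c("A", "B"))
  expect_equal(scores$genes$total[scores$genes$target_id == "B"], 0)
  expect_equal(scores$snps$target_id, "rsIN")

  ## evidence for a gene outside the window is skipped with a warning
  ev2 <- ev_tbl(ev_row(target_id = "NOWHERE"))
  expect_warning(s2 <- score_locus(locus, ev2, snp_positions = ld),
                 "NOWHERE")
  expect_true(all(s2$genes$total == 0))

  ## determinism: bit-identical tables on identical input
  a <- suppressWarnings(score_locus(locus, ev, snp_positions = ld))
  b <- suppressWarnings(score_locus(locus, ev, snp_positions = ld))
  expect_identical(a, b)
})
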