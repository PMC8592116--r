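test_that("the AR(1) LD block has the stated correlation structure", {
  blk0 <- simulate_ld_block(5, 0)
  expect_equal(blk0$R, diag(5))
  blk <- simulate_ld_block(10, 0.9)
  expect_equal(blk$R[1, 2]^2, 0.81)
  expect_equal(blk$R[3, 7], 0.9^4)
  expect_true(isSymmetric(blk$R))
  ## positive-definiteness via eigen-decomposition, across decay values
  for (rho in c(0, 0.5, 0.95, 0.999)) {
    ev <- eigen(simulate_ld_block(50, rho)$R, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(simulate_ld_block(10, 1), "rho")
  expect_equal(diff(blk$variants$pos), rep(2500L, 9))
})

test_that("null z-scores are marginally standard normal", {
  ## E|z| = sqrt(2/pi) = 0.798 under the null; average over seeded sims
  zs <- unlist(lapply(1:40, function(i) {
    cfg <- sim_config(n_snps = 50, beta = 0, beta2 = 0, seed = 1000 + i)
    sim <- simulate_joint_stats(cfg)
    c(sim$gwas$beta / sim$gwas$se, sim$qtl$beta / sim$qtl$se)
  }))
  expect_equal(mean(abs(zs)), sqrt(2 / pi), tolerance = 0.05)
  expect_equal(stats::sd(zs), 1, tolerance = 0.05)
})

test_that("joint stats are deterministic given the seed and leave the RNG alone", {
  cfg <- sim_config(n_snps = 30, seed = 7)
  a <- simulate_joint_stats(cfg)
  set.seed(99); x <- runif(1)
  b <- simulate_joint_stats(cfg)
  expect_identical(a, b)
  ## a simulator call must not perturb an ambient RNG stream
  set.seed(99); invisible(simulate_joint_stats(cfg))
  expect_identical(runif(1), x)
  expect_false(identical(a$gwas$beta,
                         simulate_joint_stats(
                           sim_config(n_snps = 30, seed = 8))$gwas$beta))
})

test_that("shared and distinct causal variants drive H4 vs H3", {
  hits <- 0
  for (i in 1:20) {
    cfg <- sim_config(n_snps = 80, causal_snp = 40, beta = 0.04,
                      beta2 = 0.25, seed = 2000 + i)
    sim <- simulate_joint_stats(cfg)
    res <- coloc_posteriors(sim$gwas, sim$qtl)
    if (res$h4 > 0.9) hits <- hits + 1
  }
  expect_gte(hits, 19)

  h3_wins <- 0
  for (i in 1:20) {
    cfg <- sim_config(n_snps = 80, causal_snp = 10, shared = FALSE,
                      causal_snp2 = 70, ld_decay = 0.9, beta = 0.04,
                      beta2 = 0.25, seed = 3000 + i)
    sim <- simulate_joint_stats(cfg)
    res <- coloc_posteriors(sim$gwas, sim$qtl)
    if (res$h3 > max(res$h0, res$h1, res$h2, res$h4)) h3_wins <- h3_wins + 1
  }
  expect_gt(h3_wins, 10)
})

test_that("evidence generation follows the plan deterministically", {
  cfg <- sim_config(n_genes = 5, planted_gene = 2, seed = 17)
  cfg$plan <- evidence_plan_strong(cfg, n_strong = 3)
  ev <- generate_evidence_set(cfg)
  expect_s3_class(ev, "evidence_tbl")
  expect_equal(sum(ev$target_id == "gene2" &
                     ev$evidence_class == "stat_full"), 3)
  expect_identical(ev, generate_evidence_set(cfg))
  expect_equal(rank_sim_genes(cfg)$target_id[1], "gene2")

  cfg$plan <- cfg$plan[0, ]
  empty <- generate_evidence_set(cfg)
  expect_equal(nrow(empty), 0)
  expect_equal(score_target("gene1", empty)$total, 0)

  cfg$plan <- data.frame(gene = 99, study_type = "eqtl",
                         evidence_class = "overlap", magnitude_mean = 0.5,
                         magnitude_sd = 0.1, n_sig = 1L, n_exp = 1L)
  expect_error(generate_evidence_set(cfg), "unknown gene")
})

test_that("the simulated annotation tiles the candidate window", {
  cfg <- sim_config(n_genes = 8, seed = 3)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 8)
  center <- cfg$start + (cfg$causal_snp - 1) * cfg$spacing
  expect_true(all(ann$start >= center - 1500000 &
                    ann$end <= center + 1500000 + 20000))
})

test_that("the packaged locus table is stored exactly as printed", {
  loci <- ad_gwas_loci()
  expect_equal(nrow(loci), 26)
  r <- loci[loci$locus_id == "11p13", ]
  expect_equal(r$index_snp, "rs2592555,rs12295535")
  expect_equal(c(r$top1, r$top1_score, r$top1_share), c("PRR5L", "598", "79"))
  expect_equal(r$top2, "TRAF6")
  expect_equal(r$top3, "COMMD9")
  hla <- loci[loci$locus_id == "6p21.32", ]
  expect_equal(hla$top1, "HLA-DRA")
  expect_equal(hla$top1_score, 1405)
  expect_equal(hla$top1_share, 30)
  ## the inconsistent printed nearest-gene cell is flagged, not corrected
  expect_true(hla$nearest_gene_suspect)
  expect_equal(hla$nearest_genes, "STAT3")
  expect_equal(sum(loci$nearest_gene_suspect), 1)
  expect_equal(sum(loci$secondary_signal), 4)
})
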