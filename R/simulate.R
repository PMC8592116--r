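## Synthetic-data generators: AR(1) LD blocks, paired GWAS/QTL z-scores
## under a shared or distinct causal variant, and evidence tables with a
## planted causal gene. All randomness flows from one mandatory seed;
## sub-streams are derived with a counter-based splitter so modules can be
## exercised independently yet reproducibly.

## Derive a 32-bit sub-seed from (seed, counter); Knuth multiplicative hash.
split_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 2654435761 + 97 * counter) %%
               .Machine$integer.max)
}

#' Simulation configuration
#'
#' @param n_snps Number of variants in the LD block.
#' @param ld_decay AR(1) correlation decay rho in [0, 1): correlation
#'   between variants i and j is rho^|i-j|.
#' @param causal_snp Index (1-based) of the causal variant; defaults to the
#'   middle of the block.
#' @param shared Does the molecular trait share the causal variant with the
#'   GWAS trait? If \code{FALSE}, \code{causal_snp2} is used for trait 2.
#' @param causal_snp2 Causal variant of trait 2 when \code{shared = FALSE}.
#' @param beta Per-allele GWAS effect size at the causal variant.
#' @param beta2 Per-allele QTL effect size (SD units of the molecular
#'   trait); cis-QTL effects are typically far larger than GWAS log-odds.
#' @param n1,n2 GWAS and QTL sample sizes.
#' @param n_genes Number of genes at the simulated locus.
#' @param planted_gene Index (1-based) of the gene given concentrated
#'   evidence.
#' @param plan Evidence plan, see \code{\link{evidence_plan_strong}}.
#' @param spacing Base-pair spacing between adjacent variants.
#' @param chrom,start Chromosome label and position of the first variant.
#' @param seed Mandatory integer seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_snps = 201, ld_decay = 0.95, causal_snp = NULL,
                       shared = TRUE, causal_snp2 = NULL, beta = 0.05,
                       beta2 = 0.25, n1 = 40000, n2 = 1000, n_genes = 8,
                       planted_gene = 3,
                       plan = NULL, spacing = 2500, chrom = "1",
                       start = 1000000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(causal_snp)) causal_snp <- (n_snps + 1) %/% 2
  stopifnot(ld_decay >= 0, ld_decay < 1, causal_snp >= 1,
            causal_snp <= n_snps, planted_gene >= 1,
            planted_gene <= n_genes)
  if (!shared && is.null(causal_snp2)) {
    stop("shared = FALSE requires causal_snp2")
  }
  structure(list(n_snps = as.integer(n_snps), ld_decay = ld_decay,
                 causal_snp = as.integer(causal_snp), shared = shared,
                 causal_snp2 = if (is.null(causal_snp2)) NULL
                   else as.integer(causal_snp2),
                 beta = beta, beta2 = beta2, n1 = n1, n2 = n2,
                 n_genes = as.integer(n_genes),
                 planted_gene = as.integer(planted_gene), plan = plan,
                 spacing = as.integer(spacing), chrom = as.character(chrom),
                 start = as.integer(start), seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror \code{\link{sim_config}}
#'   arguments.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Simulate an LD block with exponentially decaying correlation
#'
#' @param n_snps Number of variants.
#' @param rho AR(1) decay in [0, 1); \code{R[i, j] = rho^|i - j|}. The
#'   matrix is symmetric positive-definite for any such rho.
#' @param spacing,chrom,start Variant placement (equally spaced).
#' @return A list with the correlation matrix \code{R} and a data.frame
#'   \code{variants} (\code{snp_id, chrom, pos}).
#' @export
simulate_ld_block <- function(n_snps, rho, spacing = 2500, chrom = "1",
                              start = 1000000) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  idx <- seq_len(n_snps)
  R <- rho^abs(outer(idx, idx, "-"))
  variants <- data.frame(
    snp_id = sprintf("rs%05d", idx),
    chrom = chrom,
    pos = as.integer(start + (idx - 1) * spacing),
    stringsAsFactors = FALSE)
  list(R = R, variants = variants)
}

#' Simulate paired GWAS and QTL summary statistics over one LD block
#'
#' Z-scores are drawn from a multivariate normal with correlation \code{R}
#' and mean \code{R \%*\% lambda}, where \code{lambda} places the
#' noncentrality \code{beta * sqrt(n)} at the causal variant (the same
#' variant for both traits iff \code{shared}). Effect estimates are
#' back-computed with \code{se = 1 / sqrt(n)}, \code{beta_hat = z * se}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with elements \code{gwas} and \code{qtl} (summary-
#'   statistics data.frames in the package dialect), \code{ld} (per-variant
#'   r-squared to the GWAS causal variant, package LD dialect) and
#'   \code{variants}.
#' @export
simulate_joint_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  blk <- simulate_ld_block(config$n_snps, config$ld_decay, config$spacing,
                           config$chrom, config$start)
  R <- blk$R
  n <- config$n_snps
  lam1 <- rep(0, n); lam1[config$causal_snp] <- config$beta * sqrt(config$n1)
  c2 <- if (config$shared) config$causal_snp else config$causal_snp2
  lam2 <- rep(0, n); lam2[c2] <- config$beta2 * sqrt(config$n2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(config$seed, 1))
  z <- MASS::mvrnorm(2, mu = rep(0, n), Sigma = R)
  z1 <- drop(R %*% lam1) + z[1, ]
  z2 <- drop(R %*% lam2) + z[2, ]
  set.seed(split_seed(config$seed, 2))
  eaf <- stats::runif(n, 0.05, 0.95)
  mk <- function(zv, nn) {
    se <- rep(1 / sqrt(nn), n)
    data.frame(snp_id = blk$variants$snp_id, chrom = blk$variants$chrom,
               pos = blk$variants$pos, effect_allele = "A",
               other_allele = "G", beta = zv * se, se = se,
               p = 2 * stats::pnorm(-abs(zv)), eaf = eaf, n = nn,
               stringsAsFactors = FALSE)
  }
  ld <- data.frame(snp_id = blk$variants$snp_id,
                   chrom = blk$variants$chrom, pos = blk$variants$pos,
                   r2 = R[config$causal_snp, ]^2, stringsAsFactors = FALSE)
  list(gwas = mk(z1, config$n1), qtl = mk(z2, config$n2), ld = ld,
       variants = blk$variants, R = R)
}

## set.seed() clobbers the global stream; save/restore so simulators are
## pure functions of their own seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Gene annotation for a simulated locus
#'
#' Places \code{n_genes} equally spaced 20-kb genes across the 3-Mb window
#' centered on the block midpoint.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{gene_models} table with ids \code{gene1..geneN}.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  center <- config$start +
    (config$causal_snp - 1) * config$spacing
  base <- max(1, center - GENE_WINDOW_HALF)  # window clips at chrom start
  step <- (center + GENE_WINDOW_HALF - base) %/% (config$n_genes + 1)
  starts <- as.integer(base + step * seq_len(config$n_genes))
  gene_models(gene_id = paste0("gene", seq_len(config$n_genes)),
              chrom = config$chrom, start = starts, end = starts + 20000L,
              strand = rep(c("+", "-"), length.out = config$n_genes))
}

#' Evidence plans
#'
#' An evidence plan is a data.frame with one row per (gene, record) to
#' emit: columns \code{gene} (1-based gene index), \code{study_type},
#' \code{evidence_class}, \code{magnitude_mean}, \code{magnitude_sd},
#' \code{n_sig}, \code{n_exp}. \code{evidence_plan_strong} gives the
#' planted gene \code{n_strong} full-statistics records (magnitude around
#' 0.9) from distinct study types while every decoy receives one weak
#' overlap record; \code{evidence_plan_null} gives every gene one record of
#' identical class and magnitude distribution, so top rank is uniform
#' across genes.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_strong Number of full-statistics records for the planted gene.
#' @return An evidence-plan data.frame.
#' @export
evidence_plan_strong <- function(config, n_strong = 3) {
  types <- c("coloc", "twas", "finemap", "eqtl", "pqtl")
  planted <- data.frame(
    gene = config$planted_gene,
    study_type = rep_len(types, n_strong),
    evidence_class = "stat_full",
    magnitude_mean = 0.9, magnitude_sd = 0.05,
    n_sig = 1L, n_exp = 1L, stringsAsFactors = FALSE)
  decoys <- setdiff(seq_len(config$n_genes), config$planted_gene)
  bg <- data.frame(
    gene = decoys, study_type = "eqtl", evidence_class = "overlap",
    magnitude_mean = 0.4, magnitude_sd = 0.1, n_sig = 50L, n_exp = 1L,
    stringsAsFactors = FALSE)
  rbind(planted, bg)
}

#' @rdname evidence_plan_strong
#' @export
evidence_plan_null <- function(config) {
  data.frame(gene = seq_len(config$n_genes), study_type = "eqtl",
             evidence_class = "overlap", magnitude_mean = 0.5,
             magnitude_sd = 0.15, n_sig = 10L, n_exp = 1L,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic evidence table from a plan
#'
#' Magnitudes are drawn from a normal with the plan's mean and sd, then
#' clamped to [0.001, 1]; each plan row becomes one record from its own
#' study id. Deterministic given the config seed.
#'
#' @param config A \code{\link{sim_config}} whose \code{plan} is set (a
#'   plan built by \code{\link{evidence_plan_strong}} /
#'   \code{\link{evidence_plan_null}} or in the same layout).
#' @param locus_id Locus label for the emitted records.
#' @return An \code{evidence_tbl} of gene-level records.
#' @export
generate_evidence_set <- function(config, locus_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  plan <- config$plan
  if (is.null(plan)) plan <- evidence_plan_strong(config)
  if (nrow(plan) == 0) {
    return(evidence_records(data.frame(
      locus_id = character(), target_type = character(),
      target_id = character(), study_id = character(),
      study_type = character(), evidence_class = character(),
      magnitude = numeric(), stringsAsFactors = FALSE)))
  }
  if (any(plan$gene < 1 | plan$gene > config$n_genes)) {
    stop("evidence plan references an unknown gene index")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(config$seed, 3))
  mag <- pmin(1, pmax(0.001, stats::rnorm(nrow(plan), plan$magnitude_mean,
                                          plan$magnitude_sd)))
  evidence_records(data.frame(
    locus_id = locus_id, target_type = "gene",
    target_id = paste0("gene", plan$gene), linked_gene = NA_character_,
    study_id = sprintf("study%03d", seq_len(nrow(plan))),
    study_type = plan$study_type, evidence_class = plan$evidence_class,
    magnitude = mag, n_sig = plan$n_sig, n_exp = plan$n_exp,
    tissue = NA_character_, direction = NA_character_,
    stringsAsFactors = FALSE), source = "simulated evidence")
}

#' Published atopic-dermatitis locus table
#'
#' The machine-readable copy of the published prioritization summary for
#' the 25 reproducible atopic-dermatitis GWAS loci (26 rows; two loci are
#' split into independent a/b signals). Columns give, per locus, the index
#' SNP(s), the printed nearest gene(s), the top three ranked genes with
#' their integer scores and integer percentage shares of the top-10
#' cumulative score, and flags marking which top genes are the closest to
#' the index variant. Values are stored exactly as printed; the row whose
#' printed nearest-gene cell is inconsistent with its locus (a gene from
#' another chromosome) is flagged \code{nearest_gene_suspect} rather than
#' corrected.
#'
#' @return A data.frame with 26 rows, suitable for
#'   \code{\link{crosslocus_summary}}.
#' @examples
#' loci <- ad_gwas_loci()
#' crosslocus_summary(loci)
#' @export
ad_gwas_loci <- function() {
  path <- system.file("extdata", "ad_gwas_loci.tsv", package = "locusTriage",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
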