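# Independent oracles and fixture builders shared across the suite.

# Brute-force colocalization oracle: enumerate every single-causal-variant
# configuration explicitly (null; trait-1-only at i; trait-2-only at j;
# distinct pair i != j; shared variant i) and normalize the prior-weighted
# Bayes-factor masses directly. Independent of the log-sum-exp path.
coloc_enum_oracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  b1 <- exp(l1)
  b2 <- exp(l2)
  m3 <- outer(p1 * b1, p2 * b2)
  diag(m3) <- 0
  m <- c(h0 = 1, h1 = sum(p1 * b1), h2 = sum(p2 * b2), h3 = sum(m3),
         h4 = sum(p12 * b1 * b2))
  m / sum(m)
}

# Brute-force locus interval: loop over SNPs one by one.
interval_brute <- function(index_pos, ld, r2_min = 0.2, max_dist = 500000) {
  lo <- hi <- index_pos
  for (i in seq_len(nrow(ld))) {
    if (!is.na(ld$r2[i]) && ld$r2[i] >= r2_min &&
        abs(ld$pos[i] - index_pos) <= max_dist) {
      lo <- min(lo, ld$pos[i])
      hi <- max(hi, ld$pos[i])
    }
  }
  c(start = lo, end = hi)
}

# Brute-force candidate-gene scan over the full annotation.
candidates_brute <- function(window, chrom, annotation) {
  hits <- character(0)
  starts <- integer(0)
  for (i in seq_len(nrow(annotation))) {
    if (annotation$chrom[i] == chrom &&
        annotation$start[i] <= window[["end"]] &&
        annotation$end[i] >= window[["start"]]) {
      hits <- c(hits, annotation$gene_id[i])
      starts <- c(starts, annotation$start[i])
    }
  }
  hits[order(starts)]
}

# Brute-force nearest genes: edge distance over all genes, per side.
nearest_brute <- function(index_pos, annotation, chrom = NULL) {
  ann <- annotation
  if (!is.null(chrom)) ann <- ann[ann$chrom == chrom, , drop = FALSE]
  d <- pmax(0, pmax(ann$start - index_pos, index_pos - ann$end))
  if (any(d == 0)) return(unique(ann$gene_id[d == 0]))
  res <- character(0)
  up <- ann$end < index_pos
  if (any(up)) res <- c(res, ann$gene_id[up][d[up] == min(d[up])])
  dn <- ann$start > index_pos
  if (any(dn)) res <- c(res, ann$gene_id[dn][d[dn] == min(d[dn])])
  unique(res)
}

# One-call evidence row builder with sensible defaults.
ev_row <- function(locus_id = "L1", target_type = "gene",
                   target_id = "GENE1", linked_gene = NA_character_,
                   study_id = "s1", study_type = "eqtl",
                   evidence_class = "stat_full", magnitude = 0.9,
                   n_sig = 1L, n_exp = 1L, tissue = NA_character_,
                   direction = NA_character_) {
  data.frame(locus_id = locus_id, target_type = target_type,
             target_id = target_id, linked_gene = linked_gene,
             study_id = study_id, study_type = study_type,
             evidence_class = evidence_class, magnitude = magnitude,
             n_sig = n_sig, n_exp = n_exp, tissue = tissue,
             direction = direction, stringsAsFactors = FALSE)
}

ev_tbl <- function(...) evidence_records(rbind(...))

# Random small summary-statistics pair for coloc property tests. Z-scores
# are bounded so the enumeration oracle can work in plain (non-log) space.
rand_sumstats_pair <- function(n_variants) {
  ids <- paste0("v", seq_len(n_variants))
  mk <- function() {
    se <- stats::runif(n_variants, 0.02, 0.2)
    z <- stats::runif(n_variants, -12, 12)
    data.frame(snp_id = ids, beta = z * se, se = se,
               stringsAsFactors = FALSE)
  }
  list(t1 = mk(), t2 = mk())
}

# Score all simulated genes from a config's generated evidence and rank.
rank_sim_genes <- function(config, locus_id = "sim") {
  ev <- generate_evidence_set(config, locus_id)
  scores <- do.call(rbind, lapply(seq_len(config$n_genes), function(g) {
    id <- paste0("gene", g)
    ts <- score_target(id, ev, target_type = "gene")
    data.frame(target_id = id, total = ts$total, stringsAsFactors = FALSE)
  }))
  rank_targets(scores)
}

# Small deterministic gene annotation around a 102 Mb index.
demo_annotation <- function() {
  gene_models(
    gene_id = c("PRR5L", "TRAF6", "COMMD9", "FARAWAY", "OTHERCHR"),
    chrom = c("11", "11", "11", "11", "12"),
    start = c(102000000 - 40000, 102000000 - 300000, 102000000 + 200000,
              102000000 + 2000000, 102000000),
    end = c(102000000 + 20000, 102000000 - 250000, 102000000 + 260000,
            102000000 + 2100000, 102000000 + 50000),
    strand = c("+", "-", "+", "+", "+"))
}
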