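## Ranking, share metrics, locus classification and cross-locus summaries.

#' Rank targets of one locus
#'
#' Orders a score table descending by total score. Ties are broken by
#' smaller distance to the index SNP, then lexicographically by target id,
#' so rankings are stable and deterministic.
#'
#' @param scores Data.frame with \code{target_id} and \code{total} (one
#'   locus, one target type), as produced by \code{\link{score_locus}}.
#' @param distance Optional named numeric: distance (bp) from each target
#'   to the index SNP; unnamed targets get \code{Inf}.
#' @return The score table with a \code{rank} column (1..n, no gaps),
#'   ordered by rank.
#' @export
rank_targets <- function(scores, distance = NULL) {
  stopifnot(is.data.frame(scores), all(c("target_id", "total") %in%
                                         names(scores)))
  d <- rep(Inf, nrow(scores))
  if (!is.null(distance)) {
    m <- distance[scores$target_id]
    d[!is.na(m)] <- m[!is.na(m)]
  }
  ord <- order(-scores$total, d, scores$target_id, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Share of the top-m targets in the top-k cumulative score
#'
#' \code{100 * sum(score[1:m]) / sum(score[1:min(k, n)])}. Full precision is
#' retained; display rounding (half-up to integer percent) is applied by the
#' report writers only.
#'
#' @param ranked Ranked score table (descending) or numeric vector of
#'   descending scores.
#' @param k Pool size; default 10.
#' @param m Numerator size; default 1.
#' @return Percentage in [0, 100]; 0 with a warning when the pool score
#'   sums to 0.
#' @examples
#' top_share(c(598, 65, 34, 23, 14, 9, 6, 4, 3, 1))  # 79.1 -> prints as 79
#' @export
top_share <- function(ranked, k = 10, m = 1) {
  s <- if (is.data.frame(ranked)) ranked$total else as.numeric(ranked)
  n <- length(s)
  if (n == 0) return(0)
  denom <- sum(s[seq_len(min(k, n))])
  if (denom == 0) {
    warning("top-k scores sum to 0; share defined as 0", call. = FALSE)
    return(0)
  }
  100 * sum(s[seq_len(min(m, n))]) / denom
}

## Half-up rounding to integer, matching printed integer percentages
## (base round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)

#' Classify a locus by its top-gene share profile
#'
#' \code{standout} when the top gene contributes more than 50% of the
#' top-10 cumulative score; otherwise \code{shared_pair} when the top two
#' genes jointly exceed 75%; otherwise \code{ambiguous}. Classification
#' uses unrounded shares.
#'
#' @param ranked Ranked gene score table or descending score vector.
#' @param k Pool size for the shares; default 10.
#' @return One of \code{"standout"}, \code{"shared_pair"},
#'   \code{"ambiguous"}.
#' @export
classify_locus <- function(ranked, k = 10) {
  s1 <- top_share(ranked, k = k, m = 1)
  s2 <- top_share(ranked, k = k, m = 2)
  if (s1 > 50) "standout" else if (s2 > 75) "shared_pair" else "ambiguous"
}

#' Build the per-locus report
#'
#' @param locus A \code{locus_definition}.
#' @param scores Output of \code{\link{score_locus}} for the locus.
#' @param annotation Optional \code{gene_models}; used to compute gene
#'   distances to the index SNP for tie-breaking.
#' @param snp_positions Optional data.frame \code{snp_id, pos} for SNP
#'   tie-breaking and the index-SNP-is-top flag.
#' @return An object of class \code{locus_report}: ranked gene and SNP
#'   tables with \code{share_of_top10}, the locus \code{classification},
#'   \code{nearest_gene_is_top}, \code{index_snp_is_top}, and the
#'   score-decay ratio \code{decay_1_3} (top score over third score;
#'   annotated, no threshold applied).
#' @export
locus_report <- function(locus, scores, annotation = NULL,
                         snp_positions = NULL) {
  stopifnot(inherits(locus, "locus_definition"))
  gdist <- NULL
  if (!is.null(annotation)) {
    ann <- annotation[annotation$chrom == locus$chrom, , drop = FALSE]
    d <- pmax(0, pmax(ann$start - locus$index_pos,
                      locus$index_pos - ann$end))
    gdist <- stats::setNames(d, ann$gene_id)
  }
  genes <- rank_targets(scores$genes, distance = gdist)
  genes$share_of_top10 <- vapply(seq_len(nrow(genes)), function(i) {
    if (genes$total[i] == 0) 0 else
      100 * genes$total[i] / sum(genes$total[seq_len(min(10, nrow(genes)))])
  }, numeric(1))
  sdist <- NULL
  if (!is.null(snp_positions)) {
    sdist <- stats::setNames(abs(snp_positions$pos - locus$index_pos),
                             snp_positions$snp_id)
  }
  snps <- rank_targets(scores$snps, distance = sdist)
  top_gene <- if (nrow(genes) > 0 && genes$total[1] > 0) genes$target_id[1]
              else NA_character_
  top_snp <- if (nrow(snps) > 0 && snps$total[1] > 0) snps$target_id[1]
             else NA_character_
  decay <- if (nrow(genes) >= 3 && genes$total[3] > 0)
    genes$total[1] / genes$total[3] else NA_real_
  structure(list(
    locus_id = locus$locus_id,
    index_snp = locus$index_snp,
    nearest_genes = locus$nearest_genes,
    genes = genes,
    snps = snps,
    classification = classify_locus(genes),
    nearest_gene_is_top = !is.na(top_gene) &&
      top_gene %in% locus$nearest_genes,
    index_snp_is_top = if (nrow(snps) == 0) NA else
      identical(top_snp, locus$index_snp),
    decay_1_3 = decay
  ), class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("Locus %s (%s): %s\n", x$locus_id, x$index_snp,
              x$classification))
  top <- utils::head(x$genes, 3)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %d. %s  score %.1f  share %d%%\n", top$rank[i],
                top$target_id[i], top$total[i],
                round_half_up(top$share_of_top10[i])))
  }
  invisible(x)
}

## One digest row per report, mirroring the published table layout.
report_digest <- function(report) {
  g <- report$genes
  cell <- function(i, what) {
    if (nrow(g) < i) {
      return(switch(what, id = NA_character_, score = NA_real_,
                    share = NA_real_))
    }
    switch(what, id = g$target_id[i], score = g$total[i],
           share = g$share_of_top10[i])
  }
  data.frame(
    locus_id = report$locus_id, index_snp = report$index_snp,
    nearest_genes = paste(report$nearest_genes, collapse = "/"),
    top1 = cell(1, "id"), top1_score = cell(1, "score"),
    top1_share = cell(1, "share"),
    top2 = cell(2, "id"), top2_score = cell(2, "score"),
    top2_share = cell(2, "share"),
    top3 = cell(3, "id"), top3_score = cell(3, "score"),
    top3_share = cell(3, "share"),
    top1_is_nearest = report$nearest_gene_is_top,
    index_snp_is_top = report$index_snp_is_top,
    classification = report$classification,
    stringsAsFactors = FALSE
  )
}

#' Cross-locus summary of prioritization results
#'
#' Accepts either a list of \code{\link{locus_report}} objects or a
#' per-locus digest data.frame (e.g., the packaged published locus table
#' from \code{\link{ad_gwas_loci}}). When a digest lacks a
#' \code{classification} column it is derived from the (possibly printed,
#' integer) share columns: standout when top-1 share > 50, shared-pair when
#' top-1 + top-2 shares > 75.
#'
#' @param reports List of \code{locus_report}s, or a digest data.frame with
#'   columns \code{locus_id, top1, top1_score, top1_share, top2_share,
#'   top1_is_nearest} (and optionally \code{index_snp_is_top}).
#' @return A list of class \code{crosslocus_summary}: \code{n_loci},
#'   \code{nearest_gene_mismatch} (loci whose top gene is not a nearest
#'   gene), \code{index_snp_mismatch} (loci whose top SNP is not the index
#'   SNP; \code{NA} when unknown), counts per classification, the range of
#'   top-gene scores, the maximum top-gene share, and the per-locus
#'   \code{digest}.
#' @export
crosslocus_summary <- function(reports) {
  digest <- if (is.data.frame(reports)) {
    reports
  } else {
    do.call(rbind, lapply(reports, report_digest))
  }
  if (!"classification" %in% names(digest)) {
    digest$classification <- ifelse(
      digest$top1_share > 50, "standout",
      ifelse(digest$top1_share + digest$top2_share > 75, "shared_pair",
             "ambiguous"))
  }
  idx_mismatch <- if ("index_snp_is_top" %in% names(digest) &&
                      any(!is.na(digest$index_snp_is_top))) {
    sum(!digest$index_snp_is_top, na.rm = TRUE)
  } else NA_integer_
  structure(list(
    n_loci = nrow(digest),
    nearest_gene_mismatch = sum(!digest$top1_is_nearest),
    index_snp_mismatch = idx_mismatch,
    standout_count = sum(digest$classification == "standout"),
    shared_pair_count = sum(digest$classification == "shared_pair"),
    ambiguous_count = sum(digest$classification == "ambiguous"),
    min_top_score = min(digest$top1_score),
    max_top_score = max(digest$top1_score),
    max_top_share = max(digest$top1_share),
    digest = digest
  ), class = "crosslocus_summary")
}

#' @export
print.crosslocus_summary <- function(x, ...) {
  cat(sprintf("Cross-locus summary over %d loci\n", x$n_loci))
  cat(sprintf("  top gene not a nearest gene : %d\n",
              x$nearest_gene_mismatch))
  if (!is.na(x$index_snp_mismatch)) {
    cat(sprintf("  top SNP not the index SNP   : %d\n",
                x$index_snp_mismatch))
  }
  cat(sprintf("  stand-out / shared-pair / ambiguous : %d / %d / %d\n",
              x$standout_count, x$shared_pair_count, x$ambiguous_count))
  cat(sprintf("  top-gene scores range %g to %g; max top-gene share %g%%\n",
              x$min_top_score, x$max_top_score, x$max_top_share))
  invisible(x)
}

#' Write a cross-locus report TSV
#'
#' One row per locus mirroring the published table layout; shares are
#' rounded half-up to integer percent for display.
#'
#' @param summary A \code{crosslocus_summary}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_locus_report <- function(summary, path) {
  d <- summary$digest
  for (col in c("top1_share", "top2_share", "top3_share")) {
    if (col %in% names(d)) d[[col]] <- round_half_up(d[[col]])
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
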