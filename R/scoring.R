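## Scoring engine: per-record component scores and per-target totals.
##
## value  = class_weight * magnitude * specificity / sqrt(k)
##   specificity(n_sig) = 1 / (1 + log10(n_sig)) -- damps genome-wide sources
##   k = records from the same study_id supporting the same target
## total  = sum(values) * sqrt((U_type + U_id) / 2)
##   U_type / U_id = distinct study types / study ids supporting the target

#' Specificity factor of an experiment
#'
#' Experiments that report many significant SNPs or genes are less specific
#' to any one target; the factor \code{1 / (1 + log10(n))} damps them
#' logarithmically so genome-wide sources (n around 10^4) are penalized
#' without vanishing.
#'
#' @param n_sig Number of SNPs/genes the source experiment reported
#'   significant (>= 1, vectorized).
#' @return Factor(s) in (0, 1].
#' @export
specificity_factor <- function(n_sig) {
  if (any(n_sig < 1)) stop("n_sig must be >= 1")
  1 / (1 + log10(n_sig))
}

#' Independence divisor for same-study evidence
#'
#' Multiple experiments from one study (e.g., expression and methylation in
#' the same cohort) are not independent, so same-study records for a target
#' are damped by \code{sqrt(k)}. In aggregate scoring k is the record's
#' rank (strongest first) within its same-study group, which keeps totals
#' monotone under added evidence while damping study multiplicity.
#'
#' @param k Same-study multiplicity context (>= 1, vectorized).
#' @return Divisor(s) >= 1.
#' @export
independence_divisor <- function(k) {
  if (any(k < 1)) stop("k must be >= 1")
  sqrt(k)
}

#' Component score of a single evidence record
#'
#' @param record One-row \code{evidence_tbl} (or any one-row data.frame with
#'   the schema columns).
#' @param scheme A \code{\link{weight_scheme}}.
#' @param k Same-study record count for this record's target (>= 1); in
#'   aggregate scoring this is derived from the record context, see
#'   \code{\link{score_target}}.
#' @return A one-row data.frame with the weight, the three factors and the
#'   component \code{value}; the value never exceeds the class weight.
#' @examples
#' r <- evidence_records(data.frame(
#'   locus_id = "L", target_type = "gene", target_id = "G",
#'   study_id = "s1", study_type = "eqtl", evidence_class = "stat_full",
#'   magnitude = 0.9, n_sig = 100))
#' component_score(r, k = 4)$value  # 20 * 0.9 * (1/3) / 2 = 3
#' @export
component_score <- function(record, scheme = weight_scheme(), k = 1) {
  stopifnot(nrow(record) == 1)
  w <- class_weight(record$evidence_class, scheme)
  spec <- specificity_factor(record$n_sig)
  div <- independence_divisor(k)
  data.frame(target_id = record$target_id, study_id = record$study_id,
             study_type = record$study_type,
             evidence_class = record$evidence_class,
             weight = unname(w), magnitude = record$magnitude,
             specificity = spec, independence_divisor = div,
             value = unname(w) * record$magnitude * spec / div,
             stringsAsFactors = FALSE)
}

#' Heterogeneity multiplier for a target's evidence set
#'
#' Targets consistently supported by a range of evidence sources --
#' alternative assays and statistical methods -- are upweighted in
#' proportion to the square root of the mean of the number of unique study
#' types and unique study identifiers:
#' \code{sqrt((U_type + U_id) / 2)}.
#'
#' @param records \code{evidence_tbl} rows supporting one target; an empty
#'   set yields 1 (no adjustment).
#' @return Multiplier >= 1.
#' @examples
#' heterogeneity_multiplier(data.frame(study_type = letters[1:4],
#'                                     study_id = LETTERS[1:4]))  # 2
#' @export
heterogeneity_multiplier <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(1)
  u_type <- length(unique(records$study_type))
  u_id <- length(unique(records$study_id))
  sqrt((u_type + u_id) / 2)
}

## Vectorized scoring of a record set. Within each (study_id, target) group
## the j-th strongest record gets the divisor sqrt(j): diminishing returns
## for non-independent same-study experiments, yet adding a record can never
## lower the group total (the new sum minus the old is bounded below by
## new_value / sqrt(k + 1) > 0). Returns the per-record breakdown.
component_breakdown <- function(records, scheme = weight_scheme()) {
  if (nrow(records) == 0) {
    return(data.frame(target_id = character(), study_id = character(),
                      study_type = character(), evidence_class = character(),
                      weight = numeric(), magnitude = numeric(),
                      specificity = numeric(),
                      independence_divisor = numeric(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  grp <- paste(records$study_id, records$target_id, sep = "\r")
  w <- unname(class_weight(records$evidence_class, scheme))
  spec <- specificity_factor(records$n_sig)
  base <- w * records$magnitude * spec
  ## rank of each record within its same-study group, strongest first;
  ## ties resolved by row order so scoring is deterministic
  j <- stats::ave(-base, grp, FUN = function(x) rank(x, ties.method = "first"))
  div <- independence_divisor(j)
  data.frame(target_id = records$target_id, study_id = records$study_id,
             study_type = records$study_type,
             evidence_class = records$evidence_class,
             weight = w, magnitude = records$magnitude, specificity = spec,
             independence_divisor = div,
             value = w * records$magnitude * spec / div,
             stringsAsFactors = FALSE)
}

#' Total prioritization score of one target
#'
#' Sums the component scores of all records supporting the target and
#' applies the heterogeneity multiplier. For a gene target, gene-level
#' records with \code{target_id = gene} and SNP-level records whose
#' \code{linked_gene} names the gene both count.
#'
#' @param target_id Gene or variant identifier.
#' @param records \code{evidence_tbl} (pre-filtered to one locus); rows not
#'   addressing the target are ignored.
#' @param scheme A \code{\link{weight_scheme}}.
#' @param target_type \code{"gene"} or \code{"snp"}.
#' @return A list of class \code{target_score}: \code{total},
#'   \code{raw_sum}, \code{heterogeneity_multiplier},
#'   \code{n_unique_study_types}, \code{n_unique_study_ids} and the
#'   per-record \code{breakdown}.
#' @export
score_target <- function(target_id, records, scheme = weight_scheme(),
                         target_type = c("gene", "snp")) {
  target_type <- match.arg(target_type)
  sel <- if (target_type == "gene") {
    (records$target_type == "gene" & records$target_id == target_id) |
      (records$target_type == "snp" & !is.na(records$linked_gene) &
         records$linked_gene == target_id)
  } else {
    records$target_type == "snp" & records$target_id == target_id
  }
  sub <- records[sel, , drop = FALSE]
  ## independence is counted over same-study records for this target, so
  ## group key collapses to study_id here
  sub$target_id <- rep(target_id, nrow(sub))
  bd <- component_breakdown(sub, scheme)
  raw <- sum(bd$value)
  het <- heterogeneity_multiplier(sub)
  structure(list(target_id = target_id, target_type = target_type,
                 raw_sum = raw, heterogeneity_multiplier = het,
                 n_unique_study_types = length(unique(sub$study_type)),
                 n_unique_study_ids = length(unique(sub$study_id)),
                 total = raw * het, breakdown = bd),
            class = "target_score")
}

#' @export
print.target_score <- function(x, ...) {
  cat(sprintf("%s %s: total %.3f (raw %.3f x het %.3f; %d types, %d studies)\n",
              x$target_type, x$target_id, x$total, x$raw_sum,
              x$heterogeneity_multiplier, x$n_unique_study_types,
              x$n_unique_study_ids))
  invisible(x)
}

#' Score every candidate gene and interval SNP of a locus
#'
#' Gene scores are computed for the locus candidate genes only (a gene
#' without evidence scores 0); SNP scores for SNPs inside the LD interval.
#' Evidence addressing a gene outside the candidate window, or a SNP whose
#' position is unknown or outside the interval, is skipped with a warning.
#' Deterministic: identical inputs give bit-identical tables.
#'
#' @param locus A \code{locus_definition} with candidate genes attached.
#' @param evidence \code{evidence_tbl}; rows with other \code{locus_id}s are
#'   dropped.
#' @param scheme A \code{\link{weight_scheme}}.
#' @param snp_positions Optional data.frame \code{snp_id, pos} giving
#'   positions of SNP-level targets (the LD table works); used for interval
#'   membership. SNP-level records keep contributing to their
#'   \code{linked_gene} regardless of interval membership of the SNP score.
#' @return A list with data.frames \code{genes} and \code{snps} (columns
#'   \code{locus_id target_type target_id total raw_sum het_mult n_types
#'   n_studies}) and the per-record \code{breakdown}.
#' @export
score_locus <- function(locus, evidence, scheme = weight_scheme(),
                        snp_positions = NULL) {
  stopifnot(inherits(locus, "locus_definition"))
  ev <- evidence[evidence$locus_id == locus$locus_id, , drop = FALSE]

  genes <- locus$candidate_genes
  gene_targets <- unique(c(
    ev$target_id[ev$target_type == "gene"],
    ev$linked_gene[ev$target_type == "snp" & !is.na(ev$linked_gene)]))
  outside <- setdiff(gene_targets, genes)
  if (length(outside) > 0) {
    warning(sprintf("locus %s: evidence for gene(s) outside the window skipped: %s",
                    locus$locus_id, paste(outside, collapse = ", ")),
            call. = FALSE)
  }

  snp_ids <- unique(ev$target_id[ev$target_type == "snp"])
  if (length(snp_ids) > 0) {
    if (is.null(snp_positions)) {
      warning(sprintf(
        "locus %s: no SNP positions supplied; %d SNP-level target(s) skipped",
        locus$locus_id, length(snp_ids)), call. = FALSE)
      snp_in <- character(0)
    } else {
      pos <- snp_positions$pos[match(snp_ids, snp_positions$snp_id)]
      inside <- !is.na(pos) & pos >= locus$interval[["start"]] &
        pos <= locus$interval[["end"]]
      if (any(!inside)) {
        warning(sprintf(
          "locus %s: %d SNP target(s) outside the LD interval skipped",
          locus$locus_id, sum(!inside)), call. = FALSE)
      }
      snp_in <- snp_ids[inside]
    }
  } else snp_in <- character(0)

  one <- function(id, type) {
    ts <- score_target(id, ev, scheme, target_type = type)
    data.frame(locus_id = locus$locus_id, target_type = type,
               target_id = id, total = ts$total, raw_sum = ts$raw_sum,
               het_mult = ts$heterogeneity_multiplier,
               n_types = ts$n_unique_study_types,
               n_studies = ts$n_unique_study_ids,
               stringsAsFactors = FALSE)
  }
  gene_tbl <- do.call(rbind, c(lapply(genes, one, type = "gene"), list(
    data.frame(locus_id = character(), target_type = character(),
               target_id = character(), total = numeric(),
               raw_sum = numeric(), het_mult = numeric(),
               n_types = integer(), n_studies = integer(),
               stringsAsFactors = FALSE))))
  snp_tbl <- do.call(rbind, c(lapply(snp_in, one, type = "snp"), list(
    gene_tbl[0, ])))
  keep <- ev$target_type == "gene" & ev$target_id %in% genes |
    ev$target_type == "snp"
  list(genes = gene_tbl, snps = snp_tbl,
       breakdown = component_breakdown(ev[keep, , drop = FALSE], scheme))
}

#' Write score tables to TSV
#'
#' @param scores Output of \code{\link{score_locus}}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default the locus id.
#' @return Paths of the files written, invisibly.
#' @export
write_score_tables <- function(scores, dir,
                               prefix = scores$genes$locus_id[1]) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_gene_scores.tsv",
                                           "_snp_scores.tsv",
                                           "_breakdown.tsv")))
  utils::write.table(scores$genes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scores$snps, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scores$breakdown, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
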