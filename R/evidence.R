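#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the evidence schema ---------------------------

#' Evidence classes and their default weights
#'
#' Each unit of evidence entering the pipeline is assigned to one of three
#' classes reflecting the expected reliability of its producing method:
#' \describe{
#'   \item{\code{stat_full}}{results of statistical tests run on a full set
#'     of summary statistics (colocalization, TWAS/SMR, fine-mapping);
#'     default weight 20.}
#'   \item{\code{overlap}}{positional overlap of a variant or gene with
#'     significant experimental results (QTL lookups, promoter-enhancer
#'     loops, differential expression/methylation/proteome hits, GWAS-catalog
#'     entries); default weight 2.}
#'   \item{\code{prediction}}{in-silico scores from machine-learning
#'     predictors of regulatory or splicing impact; default weight 1.}
#' }
#' @name evidence-classes
NULL

EVIDENCE_CLASSES <- c("stat_full", "overlap", "prediction")

TARGET_TYPES <- c("snp", "gene")

DIRECTIONS <- c("up", "down", "na")

#' Default study-type vocabulary
#'
#' Closed (but configurable) list of source categories an evidence table may
#' declare. Unknown types are accepted with a warning and treated as their
#' own unique type by the heterogeneity adjustment.
#'
#' @return Character vector of recognized study types.
#' @export
study_type_vocabulary <- function() {
  c("eqtl", "pqtl", "mqtl", "hqtl", "caqtl", "twas", "coloc", "finemap",
    "dge", "dna_methylation_diff", "proteome_diff", "enhancer_loop", "tad",
    "ctcf", "ncrna", "tf_binding", "splice_pred", "regulatory_pred",
    "gwas_catalog")
}

## Column layout of the evidence-table TSV dialect
EVIDENCE_COLUMNS <- c("locus_id", "target_type", "target_id", "linked_gene",
                      "study_id", "study_type", "evidence_class", "magnitude",
                      "n_sig", "n_exp", "tissue", "direction")

#' Construct a weight scheme for the three evidence classes
#'
#' The scheme must preserve the ordering full-statistics > overlap >
#' prediction > 0; violating schemes are rejected at construction time so
#' class dominance is a structural guarantee of every downstream score.
#'
#' @param stat_full Weight for full-summary-statistic tests. Default 20.
#' @param overlap Weight for positional-overlap evidence. Default 2.
#' @param prediction Weight for machine-learning predictions. Default 1.
#' @return An object of class \code{weight_scheme}.
#' @examples
#' weight_scheme()
#' weight_scheme(stat_full = 10, overlap = 4, prediction = 1)
#' @export
weight_scheme <- function(stat_full = 20, overlap = 2, prediction = 1) {
  w <- c(stat_full = as.numeric(stat_full), overlap = as.numeric(overlap),
         prediction = as.numeric(prediction))
  if (anyNA(w) || any(!is.finite(w))) {
    stop("weights must be finite numbers")
  }
  if (!(w[["stat_full"]] > w[["overlap"]] &&
        w[["overlap"]] > w[["prediction"]] &&
        w[["prediction"]] > 0)) {
    stop("weight ordering violated: need stat_full > overlap > prediction > 0")
  }
  structure(as.list(w), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Evidence weight scheme:\n")
  cat(sprintf("  stat_full  %g\n  overlap    %g\n  prediction %g\n",
              x$stat_full, x$overlap, x$prediction))
  invisible(x)
}

#' Look up the weight of an evidence class
#'
#' @param evidence_class One of \code{"stat_full"}, \code{"overlap"},
#'   \code{"prediction"} (vectorized).
#' @param scheme A \code{\link{weight_scheme}}.
#' @return Numeric weight(s).
#' @examples
#' class_weight("stat_full")  # 20
#' class_weight("overlap")    # 2
#' @export
class_weight <- function(evidence_class, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  bad <- setdiff(unique(evidence_class), EVIDENCE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown evidence class: ", paste(bad, collapse = ", "))
  }
  unlist(scheme)[evidence_class]
}

#' Build a validated table of evidence records
#'
#' An evidence record is one unit of support -- a study x experiment x
#' target -- with a class, a magnitude normalized to [0, 1], and provenance
#' metadata used by the specificity, independence and heterogeneity
#' adjustments. Gene-level records must not carry a \code{linked_gene};
#' SNP-level records may name the gene their evidence points at (e.g., the
#' gene at the other end of a promoter-enhancer loop), in which case the
#' record also contributes to that gene's score.
#'
#' @param df A data.frame with (a subset of) the evidence columns; see
#'   \code{\link{read_evidence_table}} for the full dialect.
#' @param source Label used in error messages (e.g., a file name).
#' @return A validated data.frame of class \code{evidence_tbl} with all
#'   twelve schema columns in canonical order.
#' @export
evidence_records <- function(df, source = "evidence") {
  stopifnot(is.data.frame(df))
  mandatory <- c("locus_id", "target_type", "target_id", "study_id",
                 "study_type", "evidence_class", "magnitude")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing mandatory column(s): %s", source,
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(df)
  out <- data.frame(
    locus_id = as.character(df$locus_id),
    target_type = as.character(df$target_type),
    target_id = as.character(df$target_id),
    linked_gene = if ("linked_gene" %in% names(df))
      as.character(df$linked_gene) else rep(NA_character_, n),
    study_id = as.character(df$study_id),
    study_type = as.character(df$study_type),
    evidence_class = as.character(df$evidence_class),
    magnitude = as.numeric(df$magnitude),
    n_sig = if ("n_sig" %in% names(df)) as.integer(df$n_sig) else
      rep(1L, n),
    n_exp = if ("n_exp" %in% names(df)) as.integer(df$n_exp) else
      rep(1L, n),
    tissue = if ("tissue" %in% names(df)) as.character(df$tissue) else
      rep(NA_character_, n),
    direction = if ("direction" %in% names(df)) as.character(df$direction)
      else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  ## empty strings encode missing optionals in the TSV dialect
  out$linked_gene[!is.na(out$linked_gene) & out$linked_gene == ""] <- NA
  out$tissue[!is.na(out$tissue) & out$tissue == ""] <- NA
  out$direction[!is.na(out$direction) & out$direction == ""] <- NA
  ## absent metadata defaults to the most favorable value rather than
  ## silently penalizing the record
  out$n_sig[is.na(out$n_sig)] <- 1L
  out$n_exp[is.na(out$n_exp)] <- 1L

  line <- function(i) i + 1L  # 1 header line precedes row i in the file
  fail <- function(i, msg) {
    stop(sprintf("%s, line %d: %s", source, line(i), msg))
  }
  bad <- which(!out$target_type %in% TARGET_TYPES)
  if (length(bad) > 0) {
    fail(bad[1], sprintf("target_type '%s' is not one of {%s}",
                         out$target_type[bad[1]],
                         paste(TARGET_TYPES, collapse = ", ")))
  }
  bad <- which(!out$evidence_class %in% EVIDENCE_CLASSES)
  if (length(bad) > 0) {
    fail(bad[1], sprintf("evidence_class '%s' is not one of {%s}",
                         out$evidence_class[bad[1]],
                         paste(EVIDENCE_CLASSES, collapse = ", ")))
  }
  bad <- which(is.na(out$magnitude) | out$magnitude < 0 | out$magnitude > 1)
  if (length(bad) > 0) {
    fail(bad[1], sprintf("magnitude %s outside [0, 1]",
                         format(out$magnitude[bad[1]])))
  }
  bad <- which(out$n_sig < 1L | out$n_exp < 1L)
  if (length(bad) > 0) {
    fail(bad[1], "n_sig and n_exp must be >= 1")
  }
  bad <- which(out$target_type == "gene" & !is.na(out$linked_gene))
  if (length(bad) > 0) {
    fail(bad[1], "gene-level records must not carry a linked_gene")
  }
  bad <- which(!is.na(out$direction) & !out$direction %in% DIRECTIONS)
  if (length(bad) > 0) {
    fail(bad[1], sprintf("direction '%s' is not one of {%s}",
                         out$direction[bad[1]],
                         paste(DIRECTIONS, collapse = ", ")))
  }
  unknown <- setdiff(unique(out$study_type), study_type_vocabulary())
  if (length(unknown) > 0) {
    warning(sprintf("%s: study_type(s) outside the default vocabulary: %s",
                    source, paste(unknown, collapse = ", ")),
            call. = FALSE)
  }
  class(out) <- c("evidence_tbl", "data.frame")
  out
}

#' Read an evidence table
#'
#' Parses the pipeline's tab-delimited evidence dialect: UTF-8, header row
#' \code{locus_id target_type target_id linked_gene study_id study_type
#' evidence_class magnitude n_sig n_exp tissue direction}, empty string for
#' missing optionals. Unknown extra columns are ignored with a warning; an
#' empty file (header only) yields an empty record collection.
#'
#' @param path Path to a TSV file.
#' @return A validated \code{evidence_tbl}; row order preserved.
#' @seealso \code{\link{write_evidence_table}}
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  extra <- setdiff(names(raw), EVIDENCE_COLUMNS)
  if (length(extra) > 0) {
    warning(sprintf("%s: ignoring extra column(s): %s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  if (nrow(raw) == 0) {
    return(evidence_records(
      data.frame(locus_id = character(), target_type = character(),
                 target_id = character(), study_id = character(),
                 study_type = character(), evidence_class = character(),
                 magnitude = numeric(), stringsAsFactors = FALSE),
      source = path))
  }
  evidence_records(raw, source = path)
}

#' Write an evidence table
#'
#' Inverse of \code{\link{read_evidence_table}}: the round trip through disk
#' reproduces every field value exactly.
#'
#' @param records An \code{evidence_tbl}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_evidence_table <- function(records, path) {
  stopifnot(inherits(records, "evidence_tbl"))
  out <- as.data.frame(records)[, EVIDENCE_COLUMNS]
  for (col in c("linked_gene", "tissue", "direction")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize a producer statistic to the [0, 1] magnitude scale
#'
#' The scoring engine is agnostic to source statistics: producers map their
#' native statistic onto [0, 1] at ingestion. The default registry covers
#' the common producers: colocalization posteriors and fine-mapping
#' posterior inclusion probabilities pass through; p-value-based lookups map
#' through \code{min(1, -log10(p) / 10)}; binary overlap hits map to 1;
#' predictor scores are assumed provider-normalized to [0, 1].
#'
#' @param value Native statistic value(s).
#' @param kind One of \code{"posterior"}, \code{"pvalue"}, \code{"binary"},
#'   \code{"unit"}.
#' @return Magnitude(s) in [0, 1].
#' @examples
#' normalize_magnitude(1e-8, "pvalue")  # 0.8
#' normalize_magnitude(0.93, "posterior")
#' @export
normalize_magnitude <- function(value,
                                kind = c("posterior", "pvalue", "binary",
                                         "unit")) {
  kind <- match.arg(kind)
  switch(kind,
    posterior = ,
    unit = {
      if (any(value < 0 | value > 1, na.rm = TRUE)) {
        stop(kind, " values must already lie in [0, 1]")
      }
      value
    },
    pvalue = {
      if (any(value <= 0 | value > 1, na.rm = TRUE)) {
        stop("p-values must lie in (0, 1]")
      }
      pmin(1, -log10(value) / 10)
    },
    binary = as.numeric(value != 0)
  )
}
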