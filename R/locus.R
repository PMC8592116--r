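## Locus geometry: LD-based intervals, candidate-gene windows, nearest genes.
## All coordinates are 1-based inclusive internally; BED input (0-based
## half-open) is converted at the reader boundary.

LOCUS_MAX_DIST <- 500000L     # LD-interval cap, bp per side
GENE_WINDOW_HALF <- 1500000L  # candidate-gene window, bp per side (3 Mb total)

#' Build a table of gene models
#'
#' @param gene_id Gene identifiers.
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive gene-body bounds (bp).
#' @param strand \code{"+"} or \code{"-"}; determines the transcription
#'   start site (\code{start} on +, \code{end} on -), which is used for
#'   cis-window eligibility. Nearest-gene distances use gene-body edges.
#' @param symbol Optional display symbols (defaults to \code{gene_id}).
#' @return A data.frame of class \code{gene_models} with a derived
#'   \code{tss} column.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "+",
                        symbol = gene_id) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("gene start must be <= end")
  strand <- rep_len(as.character(strand), length(gene_id))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    chrom = as.character(chrom),
                    start = start, end = end, strand = strand,
                    tss = ifelse(strand == "+", start, end),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read gene annotation from BED6 or GFF3
#'
#' Uses \pkg{rtracklayer} for parsing; BED 0-based half-open coordinates
#' are converted to the package's 1-based inclusive convention (rtracklayer
#' already returns 1-based GRanges). For GFF3, rows of type \code{gene} are
#' kept and the \code{ID} (or \code{Name}) attribute becomes the gene id.
#'
#' @param path Path to a \code{.bed} or \code{.gff3}/\code{.gff} file.
#' @return A \code{gene_models} table.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading BED/GFF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  if ("type" %in% names(meta)) meta <- meta[meta$type == "gene", ]
  id <- if ("name" %in% names(meta)) meta$name
        else if ("ID" %in% names(meta)) meta$ID
        else if ("Name" %in% names(meta)) meta$Name
        else paste0("gene", seq_len(nrow(meta)))
  strand <- as.character(meta$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  gene_models(gene_id = id, chrom = as.character(meta$seqnames),
              start = meta$start, end = meta$end, strand = strand)
}

#' Read an LD table
#'
#' Expects the dialect \code{snp_id chrom pos r2} with r-squared measured
#' against the locus index SNP.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns \code{snp_id, chrom, pos, r2}.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ld <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "")
  need <- c("snp_id", "chrom", "pos", "r2")
  miss <- setdiff(need, names(ld))
  if (length(miss) > 0) {
    stop(path, ": missing LD column(s): ", paste(miss, collapse = ", "))
  }
  ld$pos <- as.integer(ld$pos)
  ld$r2 <- as.numeric(ld$r2)
  if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE)) stop("r2 outside [0, 1]")
  ld[, need]
}

#' Define the GWAS locus interval from LD with the index SNP
#'
#' The interval runs from the furthest 5' to the furthest 3' SNP with
#' r-squared at least \code{r2_min} to the index SNP, with each side capped
#' at \code{max_dist} bp. A SNP beyond the cap never qualifies, so a side
#' with no qualifying SNP collapses to the index position (the cap truncates
#' the boundary; it does not discard the locus). With no qualifying SNPs at
#' all, the degenerate interval \code{[index_pos, index_pos]} is returned
#' with a warning.
#'
#' @param index_pos 1-based position of the index SNP (bp).
#' @param ld A data.frame with columns \code{pos} and \code{r2} (r-squared
#'   to the index SNP), same chromosome as the index.
#' @param r2_min LD threshold; default 0.2.
#' @param max_dist Per-side cap in bp; default 500,000.
#' @return Integer vector \code{c(start, end)}, 1-based inclusive.
#' @examples
#' ld <- data.frame(pos = c(101700000, 102300000, 102800000),
#'                  r2  = c(0.35, 0.21, 0.9))
#' define_locus_interval(102000000, ld)  # c(101700000, 102300000)
#' @export
define_locus_interval <- function(index_pos, ld, r2_min = 0.2,
                                  max_dist = LOCUS_MAX_DIST) {
  index_pos <- as.integer(index_pos)
  stopifnot(length(index_pos) == 1, r2_min >= 0, max_dist >= 0)
  if (is.null(ld) || nrow(ld) == 0) {
    warning("no qualifying LD SNPs; degenerate interval at the index SNP",
            call. = FALSE)
    return(c(start = index_pos, end = index_pos))
  }
  if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE)) stop("r2 outside [0, 1]")
  ok <- !is.na(ld$r2) & ld$r2 >= r2_min &
    abs(ld$pos - index_pos) <= max_dist
  if (!any(ok)) {
    warning("no qualifying LD SNPs; degenerate interval at the index SNP",
            call. = FALSE)
    return(c(start = index_pos, end = index_pos))
  }
  pos <- as.integer(ld$pos[ok])
  c(start = min(c(pos, index_pos)), end = max(c(pos, index_pos)))
}

#' Assemble a locus definition
#'
#' Combines the LD interval, the 3-Mb candidate-gene window centered on the
#' index SNP, the candidate-gene list and the nearest-gene annotation into
#' one object. When secondary index SNPs are given (independent signals
#' reported on one row), the interval is the union of the per-index LD
#' intervals and the gene window is the union of the per-index windows.
#'
#' @param locus_id Locus label (e.g., a cytogenetic band).
#' @param index_snp Index variant id.
#' @param chrom Chromosome label.
#' @param index_pos Index variant position (bp).
#' @param ld LD table for the locus (see \code{\link{define_locus_interval}}).
#' @param annotation A \code{gene_models} table.
#' @param secondary List of \code{list(snp =, pos =, ld =)} entries for
#'   secondary independent signals; optional.
#' @param r2_min,max_dist Passed to \code{\link{define_locus_interval}}.
#' @return An object of class \code{locus_definition}.
#' @export
locus_definition <- function(locus_id, index_snp, chrom, index_pos, ld = NULL,
                             annotation = NULL, secondary = NULL,
                             r2_min = 0.2, max_dist = LOCUS_MAX_DIST) {
  index_pos <- as.integer(index_pos)
  interval <- define_locus_interval(index_pos, ld, r2_min, max_dist)
  window <- c(start = max(1L, index_pos - GENE_WINDOW_HALF),
              end = index_pos + GENE_WINDOW_HALF)
  sec_ids <- character(0)
  if (!is.null(secondary)) {
    for (s in secondary) {
      sec_ids <- c(sec_ids, s$snp)
      iv <- define_locus_interval(as.integer(s$pos), s$ld, r2_min, max_dist)
      interval <- c(start = min(interval[["start"]], iv[["start"]]),
                    end = max(interval[["end"]], iv[["end"]]))
      window <- c(start = max(1L, min(window[["start"]],
                                      as.integer(s$pos) - GENE_WINDOW_HALF)),
                  end = max(window[["end"]],
                            as.integer(s$pos) + GENE_WINDOW_HALF))
    }
  }
  locus <- structure(list(
    locus_id = as.character(locus_id),
    index_snp = as.character(index_snp),
    chrom = as.character(chrom),
    index_pos = index_pos,
    interval = interval,
    gene_window = window,
    candidate_genes = character(0),
    nearest_genes = character(0),
    secondary_index_snps = sec_ids
  ), class = "locus_definition")
  if (!is.null(annotation)) {
    locus$candidate_genes <- candidate_genes(locus, annotation)
    ## nearest-gene search is window-restricted so the nearest genes are
    ## always scored candidates
    wnd <- annotation[annotation$chrom == locus$chrom &
                        annotation$start <= window[["end"]] &
                        annotation$end >= window[["start"]], , drop = FALSE]
    locus$nearest_genes <- if (nrow(wnd) > 0) {
      nearest_genes(index_pos, wnd, chrom = locus$chrom)
    } else character(0)
  }
  locus
}

#' @export
print.locus_definition <- function(x, ...) {
  cat(sprintf("Locus %s  index %s (%s:%s)\n", x$locus_id, x$index_snp,
              x$chrom, format(x$index_pos, big.mark = ",")))
  cat(sprintf("  LD interval  [%s, %s]\n",
              format(x$interval[["start"]], big.mark = ","),
              format(x$interval[["end"]], big.mark = ",")))
  cat(sprintf("  gene window  [%s, %s]\n",
              format(x$gene_window[["start"]], big.mark = ","),
              format(x$gene_window[["end"]], big.mark = ",")))
  cat(sprintf("  %d candidate gene(s); nearest: %s\n",
              length(x$candidate_genes),
              paste(x$nearest_genes, collapse = ", ")))
  invisible(x)
}

#' Genes overlapping the candidate window of a locus
#'
#' A gene is a candidate when its body overlaps the 3-Mb window centered on
#' the index SNP; overlap is inclusive at both ends. Genes are returned
#' ordered by start position.
#'
#' @param locus A \code{locus_definition}.
#' @param annotation A \code{gene_models} table.
#' @return Character vector of gene ids, ordered by gene start.
#' @export
candidate_genes <- function(locus, annotation) {
  stopifnot(inherits(locus, "locus_definition"),
            inherits(annotation, "gene_models"))
  ann <- annotation[annotation$chrom == locus$chrom, , drop = FALSE]
  if (nrow(ann) == 0) {
    warning(sprintf("locus %s: no annotation on chromosome %s",
                    locus$locus_id, locus$chrom), call. = FALSE)
    return(character(0))
  }
  hit <- ann$start <= locus$gene_window[["end"]] &
    ann$end >= locus$gene_window[["start"]]
  ann <- ann[hit, , drop = FALSE]
  ann$gene_id[order(ann$start)]
}

#' Nearest gene(s) to the index variant
#'
#' Distance is measured from the index position to the closer gene-body
#' edge. When the index falls inside a gene, that gene (distance 0) is the
#' unique nearest gene; otherwise the nearest gene on each side (upstream
#' and downstream) is returned. Equal-distance ties on a side return all
#' tied genes, with a message.
#'
#' @param index_pos Index variant position (bp).
#' @param annotation A \code{gene_models} table.
#' @param chrom Optional chromosome filter.
#' @return Character vector of 1-2 gene ids (more under ties).
#' @export
nearest_genes <- function(index_pos, annotation, chrom = NULL) {
  stopifnot(inherits(annotation, "gene_models"), nrow(annotation) > 0)
  ann <- annotation
  if (!is.null(chrom)) ann <- ann[ann$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0) return(character(0))
  inside <- ann$start <= index_pos & ann$end >= index_pos
  if (any(inside)) return(unique(ann$gene_id[inside]))
  res <- character(0)
  up <- ann[ann$end < index_pos, , drop = FALSE]
  if (nrow(up) > 0) {
    d <- index_pos - up$end
    tied <- up$gene_id[d == min(d)]
    if (length(tied) > 1) {
      message("nearest-gene tie upstream: ", paste(tied, collapse = ", "))
    }
    res <- c(res, tied)
  }
  dn <- ann[ann$start > index_pos, , drop = FALSE]
  if (nrow(dn) > 0) {
    d <- dn$start - index_pos
    tied <- dn$gene_id[d == min(d)]
    if (length(tied) > 1) {
      message("nearest-gene tie downstream: ", paste(tied, collapse = ", "))
    }
    res <- c(res, tied)
  }
  unique(res)
}
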