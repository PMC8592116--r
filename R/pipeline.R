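## End-to-end orchestration: interval -> candidate genes -> colocalization
## -> evidence merge -> scoring -> ranking -> report, per locus.

#' Assemble a run configuration
#'
#' @param loci List of per-locus entries, each a list with \code{locus_id},
#'   \code{index_snp}, \code{chrom}, \code{index_pos}, an optional
#'   \code{ld} table (data.frame or TSV path) and optional \code{secondary}
#'   signals (see \code{\link{locus_definition}}).
#' @param annotation Gene annotation: a \code{gene_models} table or a
#'   BED/GFF path.
#' @param evidence Optional ingested evidence: an \code{evidence_tbl} or a
#'   TSV path.
#' @param gwas Optional GWAS summary statistics (data.frame or TSV path);
#'   required when \code{qtl} datasets are configured.
#' @param qtl Optional list of QTL datasets for colocalization, each a list
#'   with \code{study_id}, \code{gene_id}, \code{stats} (data.frame or TSV
#'   path) and optional \code{study_type}, \code{tissue}, \code{prior_sd}.
#' @param weights A \code{\link{weight_scheme}} or list of overrides.
#' @param priors Colocalization priors: list with \code{p1, p2, p12}.
#' @param h4_min Colocalization inclusion threshold; default 0.5.
#' @param outdir Output directory (\code{NULL} disables writing).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(loci, annotation, evidence = NULL, gwas = NULL,
                       qtl = NULL, weights = weight_scheme(),
                       priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                       h4_min = 0.5, outdir = NULL, seed = 1L) {
  if (length(loci) == 0) stop("locus list must be non-empty")
  if (!inherits(weights, "weight_scheme")) {
    weights <- do.call(weight_scheme, as.list(weights))
  }
  structure(list(loci = loci, annotation = annotation, evidence = evidence,
                 gwas = gwas, qtl = qtl, weights = weights, priors = priors,
                 h4_min = h4_min, outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Path-valued fields are resolved relative to the YAML file's directory
#' and checked for existence at validation time.
#'
#' @param path YAML file whose keys mirror \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && length(p) == 1) {
      full <- if (file.exists(p)) p else file.path(base, p)
      if (!file.exists(full)) stop("configured path does not exist: ", p)
      full
    } else p
  }
  cfg$annotation <- resolve(cfg$annotation)
  cfg$evidence <- resolve(cfg$evidence)
  cfg$gwas <- resolve(cfg$gwas)
  if (!is.null(cfg$qtl)) {
    cfg$qtl <- lapply(cfg$qtl, function(q) { q$stats <- resolve(q$stats); q })
  }
  if (!is.null(cfg$loci)) {
    cfg$loci <- lapply(cfg$loci, function(l) {
      if (!is.null(l$ld)) l$ld <- resolve(l$ld)
      l
    })
  }
  do.call(run_config, cfg)
}

as_annotation <- function(x) {
  if (inherits(x, "gene_models")) x else read_gene_annotation(x)
}
as_evidence <- function(x) {
  if (is.null(x)) {
    return(evidence_records(data.frame(
      locus_id = character(), target_type = character(),
      target_id = character(), study_id = character(),
      study_type = character(), evidence_class = character(),
      magnitude = numeric(), stringsAsFactors = FALSE)))
  }
  if (inherits(x, "evidence_tbl")) x else read_evidence_table(x)
}
as_sumstats <- function(x, trait = "trait") {
  if (is.null(x) || is.data.frame(x)) x else read_sumstats(x, trait)
}
as_ld <- function(x) {
  if (is.null(x) || is.data.frame(x)) x else read_ld_table(x)
}

#' Run the full prioritization pipeline
#'
#' For each configured locus: define the LD interval and the 3-Mb gene
#' window, select candidate genes, run colocalization against each
#' configured QTL dataset (qualifying results become full-statistics
#' evidence records), merge with ingested evidence, score genes and SNPs,
#' rank, and build the locus report. A stage failure aborts that locus
#' with a logged error and the run continues; the returned object records
#' which loci failed.
#'
#' @param config A \code{\link{run_config}} (or a YAML path).
#' @return A list of class \code{pipeline_result}: \code{reports} (one
#'   \code{locus_report} per successful locus), \code{summary} (a
#'   \code{\link{crosslocus_summary}}), \code{coloc} (per-pair results),
#'   \code{failed} (locus ids), and \code{manifest}. With \code{outdir}
#'   set, score tables, the locus report TSV and a YAML manifest are
#'   written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  annotation <- as_annotation(config$annotation)
  ingested <- as_evidence(config$evidence)
  gwas <- as_sumstats(config$gwas, "gwas")

  reports <- list()
  coloc_log <- list()
  failed <- character(0)
  for (entry in config$loci) {
    res <- tryCatch({
      ld <- as_ld(entry$ld)
      locus <- locus_definition(entry$locus_id, entry$index_snp,
                                entry$chrom, entry$index_pos, ld = ld,
                                annotation = annotation,
                                secondary = entry$secondary)
      ev <- ingested
      for (q in config$qtl %||% list()) {
        if (!q$gene_id %in% locus$candidate_genes) next
        qstats <- as_sumstats(q$stats, q$study_id)
        cres <- coloc_posteriors(
          gwas, qstats,
          p1 = config$priors$p1, p2 = config$priors$p2,
          p12 = config$priors$p12,
          prior_sd2 = q$prior_sd %||% 0.15)
        coloc_log[[length(coloc_log) + 1]] <- data.frame(
          locus_id = locus$locus_id, study_id = q$study_id,
          gene_id = q$gene_id, h0 = cres$h0, h1 = cres$h1, h2 = cres$h2,
          h3 = cres$h3, h4 = cres$h4, n_variants = cres$n_variants,
          stringsAsFactors = FALSE)
        rec <- coloc_to_evidence(cres, locus$locus_id, q$gene_id,
                                 q$study_id,
                                 study_type = q$study_type %||% "coloc",
                                 tissue = q$tissue %||% NA,
                                 h4_min = config$h4_min)
        if (!is.null(rec)) ev <- rbind_evidence(ev, rec)
      }
      scores <- score_locus(locus, ev, config$weights,
                            snp_positions = ld)
      locus_report(locus, scores, annotation = annotation,
                   snp_positions = ld)
    }, error = function(e) {
      message(sprintf("locus %s failed: %s", entry$locus_id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, entry$locus_id)
    else reports[[entry$locus_id]] <- res
  }

  summary <- if (length(reports) > 0) crosslocus_summary(reports) else NULL
  manifest <- list(
    seed = config$seed,
    n_loci = length(config$loci),
    n_failed = length(failed),
    weights = unclass(config$weights),
    priors = config$priors,
    h4_min = config$h4_min,
    package_version = as.character(utils::packageVersion("locusTriage"))
  )
  out <- structure(list(reports = reports, summary = summary,
                        coloc = do.call(rbind, coloc_log),
                        failed = failed, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_output(out, config$outdir)
  out
}

rbind_evidence <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("evidence_tbl", "data.frame")
  out
}

write_pipeline_output <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (rep in result$reports) {
    utils::write.table(rep$genes,
                       file.path(outdir,
                                 paste0(rep$locus_id, "_gene_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$snps,
                       file.path(outdir,
                                 paste0(rep$locus_id, "_snp_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$summary)) {
    write_locus_report(result$summary, file.path(outdir,
                                                 "locus_report.tsv"))
  }
  if (!is.null(result$coloc)) {
    utils::write.table(result$coloc, file.path(outdir, "coloc_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(result$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d locus report(s), %d failure(s)\n",
              length(x$reports), length(x$failed)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
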