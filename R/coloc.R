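## Approximate-Bayes-factor colocalization for one GWAS x QTL locus pair.
## Single-causal-variant model over hypotheses H0-H4; per-variant Wakefield
## log-ABFs combined in log space with log-sum-exp.

#' Wakefield approximate log Bayes factor for one variant
#'
#' Under a normal prior N(0, prior_sd^2) on the effect and a normal
#' likelihood for the estimate, the log Bayes factor of association against
#' the null is \code{0.5 * (log(1 - r) + r * z^2)} with shrinkage
#' \code{r = prior_sd^2 / (se^2 + prior_sd^2)} and \code{z = beta / se}.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s); must be positive.
#' @param prior_sd Prior standard deviation of the true effect; 0.15 is the
#'   conventional default for quantitative traits, 0.2 for case-control
#'   log-odds.
#' @return Log Bayes factor(s), same length as \code{beta}.
#' @examples
#' log_abf(0.1, 0.05, 0.2)  # 0.46575
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd < 0)) stop("prior_sd must be non-negative")
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Read a summary-statistics table
#'
#' Dialect: tab-delimited with header \code{snp_id chrom pos effect_allele
#' other_allele beta se p eaf n}.
#'
#' @param path Path to a TSV file.
#' @param trait Optional trait label attached as attribute.
#' @return A data.frame of per-variant summary statistics.
#' @export
read_sumstats <- function(path, trait = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "")
  need <- c("snp_id", "beta", "se")
  miss <- setdiff(need, names(ss))
  if (length(miss) > 0) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(ss$se <= 0, na.rm = TRUE)) stop(path, ": se must be positive")
  attr(ss, "trait") <- trait
  ss
}

is_palindromic <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}

## Inner-join two summary-statistics tables on snp_id and align trait2's
## effects to trait1's effect allele. Strand-ambiguous (A/T, C/G) variants
## are dropped with a warning; allele-incompatible variants are dropped too.
harmonize_sumstats <- function(trait1, trait2) {
  shared <- intersect(trait1$snp_id, trait2$snp_id)
  if (length(shared) == 0) {
    stop(sprintf("no shared variants between traits '%s' and '%s'",
                 attr(trait1, "trait") %||% "trait1",
                 attr(trait2, "trait") %||% "trait2"))
  }
  t1 <- trait1[match(shared, trait1$snp_id), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$snp_id), , drop = FALSE]
  if (all(c("effect_allele", "other_allele") %in% names(t1)) &&
      all(c("effect_allele", "other_allele") %in% names(t2))) {
    pal <- is_palindromic(t1$effect_allele, t1$other_allele)
    if (any(pal)) {
      warning(sprintf("dropping %d strand-ambiguous (A/T, C/G) variant(s)",
                      sum(pal)), call. = FALSE)
    }
    same <- toupper(t1$effect_allele) == toupper(t2$effect_allele) &
      toupper(t1$other_allele) == toupper(t2$other_allele)
    flip <- toupper(t1$effect_allele) == toupper(t2$other_allele) &
      toupper(t1$other_allele) == toupper(t2$effect_allele)
    t2$beta[flip] <- -t2$beta[flip]
    keep <- !pal & (same | flip)
    if (!any(keep)) stop("no allele-compatible shared variants")
    t1 <- t1[keep, , drop = FALSE]
    t2 <- t2[keep, , drop = FALSE]
  }
  list(trait1 = t1, trait2 = t2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Colocalization posteriors for two traits at one locus
#'
#' Enumerates the five single-causal-variant hypotheses -- H0 neither trait
#' associated, H1/H2 only trait 1/2, H3 both but distinct causal variants,
#' H4 both sharing one causal variant -- and returns their posterior
#' probabilities given per-variant approximate Bayes factors and the prior
#' probabilities that a variant is causal for trait 1 (\code{p1}), trait 2
#' (\code{p2}) or both (\code{p12}). All sums are accumulated in log space.
#'
#' @param trait1,trait2 Per-variant summary statistics (data.frames with at
#'   least \code{snp_id}, \code{beta}, \code{se}); variants are inner-joined
#'   on \code{snp_id} and allele-harmonized when allele columns are present.
#' @param p1,p2,p12 Prior probabilities; defaults 1e-4, 1e-4, 1e-5.
#' @param prior_sd1,prior_sd2 Effect-scale prior SD per trait; default 0.15.
#' @return An object of class \code{coloc_result}: posteriors \code{h0..h4},
#'   \code{n_variants}, the priors, and \code{top_shared_variant} (the
#'   variant with the largest summed log-ABF).
#' @examples
#' t1 <- data.frame(snp_id = c("a", "b", "c"), beta = c(0, 0.8, 0),
#'                  se = 0.1)
#' t2 <- data.frame(snp_id = c("a", "b", "c"), beta = c(0, 0.75, 0),
#'                  se = 0.1)
#' coloc_posteriors(t1, t2)$h4  # close to 1
#' @export
coloc_posteriors <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5, prior_sd1 = 0.15,
                             prior_sd2 = 0.15) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0)
  h <- harmonize_sumstats(trait1, trait2)
  t1 <- h$trait1; t2 <- h$trait2
  n <- nrow(t1)
  if (n < 2) stop("colocalization needs at least 2 shared variants")
  l1 <- log_abf(t1$beta, t1$se, prior_sd1)
  l2 <- log_abf(t2$beta, t2$se, prior_sd2)
  if (any(!is.finite(l1)) || any(!is.finite(l2))) {
    stop("non-finite log-ABF encountered")
  }
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    ## sum over ordered pairs i != j equals (sum_i)(sum_j) - sum_{i=j}
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  post <- exp(lh - logsumexp(lh))
  structure(list(
    h0 = post[["h0"]], h1 = post[["h1"]], h2 = post[["h2"]],
    h3 = post[["h3"]], h4 = post[["h4"]],
    n_variants = n,
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    top_shared_variant = t1$snp_id[which.max(l1 + l2)]
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants\n", x$n_variants))
  cat(sprintf("  H0 %.4f  H1 %.4f  H2 %.4f  H3 %.4f  H4 %.4f\n",
              x$h0, x$h1, x$h2, x$h3, x$h4))
  cat(sprintf("  top shared variant: %s\n", x$top_shared_variant))
  invisible(x)
}

#' Convert a qualifying colocalization result into an evidence record
#'
#' A colocalization is informative enough to enter the score only when the
#' posterior probability of the shared-causal-variant hypothesis exceeds
#' \code{h4_min} (strictly). Qualifying results become gene-level
#' \code{stat_full} records with magnitude equal to the H4 posterior.
#'
#' @param result A \code{coloc_result}.
#' @param locus_id,gene_id Locus and gene the pair addresses.
#' @param study_id Identifier of the QTL study.
#' @param study_type QTL study type; default \code{"coloc"}.
#' @param tissue Optional tissue label.
#' @param h4_min Inclusion threshold on the H4 posterior; default 0.5.
#' @return An \code{evidence_tbl} with one row, or \code{NULL} when the
#'   result does not qualify.
#' @export
coloc_to_evidence <- function(result, locus_id, gene_id, study_id,
                              study_type = "coloc", tissue = NA,
                              h4_min = 0.5) {
  stopifnot(inherits(result, "coloc_result"))
  if (!(result$h4 > h4_min)) return(NULL)
  evidence_records(data.frame(
    locus_id = locus_id, target_type = "gene", target_id = gene_id,
    linked_gene = NA_character_, study_id = study_id,
    study_type = study_type, evidence_class = "stat_full",
    magnitude = result$h4, n_sig = 1L, n_exp = 1L,
    tissue = as.character(tissue), direction = NA_character_,
    stringsAsFactors = FALSE
  ), source = "coloc")
}
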