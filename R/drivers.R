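#' Functional-consequence filter for driver discovery
#'
#' The first stage of the driver cascade. Protein-truncating (stop-gain,
#' stop-loss, frameshift) and splice-site mutations are always retained.
#' Missense substitutions are excluded only when both predictors agree the
#' effect is moderate/benign: SIFT score > 0.2 AND PolyPhen2 score < 0.8.
#' A missing score cannot demonstrate benignity, so missense variants with
#' incomplete scores are retained. Synonymous, UTR and intergenic changes
#' never enter the cascade. If a logical `low_quality` column is present
#' (the hook standing in for manual read inspection), flagged variants are
#' excluded.
#'
#' @param variants variant data.frame with `consequence` and (for
#'   missense) `sift`/`polyphen2` columns.
#' @return logical vector: TRUE where the variant survives.
#' @examples
#' v <- data.frame(consequence = c("missense", "missense", "stop-gain"),
#'                 sift = c(0.05, 0.5, NA), polyphen2 = c(0.87, 0.5, NA))
#' functional_filter(v)  # TRUE FALSE TRUE
#' @export
functional_filter <- function(variants) {
  cons <- variants$consequence
  truncating <- cons %in% c("stop-gain", "stop-loss", "frameshift",
                            "splice-site")
  sift <- variants$sift %||% rep(NA_real_, nrow(variants))
  pp2 <- variants$polyphen2 %||% rep(NA_real_, nrow(variants))
  benign <- !is.na(sift) & !is.na(pp2) & sift > 0.2 & pp2 < 0.8
  keep <- truncating | (cons %in% "missense" & !benign)
  if (!is.null(variants$low_quality))
    keep <- keep & !(variants$low_quality %in% TRUE)
  keep
}

#' Build the gene-by-sample driver matrix
#'
#' Summarizes filtered coding variants into a gene x sample structure:
#' per-cell mutation counts plus per-cell flags for the presence of a
#' truncating mutation, LOH at the locus, and focal amplification. Genes
#' appear as rows only if at least one cell is non-zero or flagged.
#' Variants without a gene annotation are skipped and counted.
#'
#' @param variants filtered variant data.frame with `sample`, `gene`,
#'   `consequence`, optional logical `loh` column.
#' @param amplification_calls optional data.frame (`sample`, `gene`) of
#'   focal amplification events to merge in.
#' @param loh_calls optional data.frame (`sample`, `gene`) of LOH calls to
#'   merge in (in addition to any per-variant `loh` column).
#' @return object of class `gene_sample_matrix`: list with integer matrix
#'   `counts` and logical matrices `truncating`, `loh`, `amplified`
#'   (same dimnames), plus `n_skipped`.
#' @export
build_gene_sample_matrix <- function(variants, amplification_calls = NULL,
                                     loh_calls = NULL) {
  has_gene <- !is.na(variants$gene) & variants$gene != ""
  n_skipped <- sum(!has_gene)
  v <- variants[has_gene, , drop = FALSE]
  genes <- sort(unique(c(v$gene, amplification_calls$gene, loh_calls$gene)))
  samples <- sort(unique(c(v$sample, amplification_calls$sample,
                           loh_calls$sample)))
  mk <- function(mode) matrix(if (mode == "i") 0L else FALSE,
                              nrow = length(genes), ncol = length(samples),
                              dimnames = list(genes, samples))
  counts <- mk("i"); trunc <- mk("l"); loh <- mk("l"); amp <- mk("l")
  if (nrow(v)) {
    tab <- table(factor(v$gene, levels = genes),
                 factor(v$sample, levels = samples))
    counts[] <- as.integer(tab)
    is_tr <- v$consequence %in% c("stop-gain", "stop-loss", "frameshift")
    for (i in which(is_tr)) trunc[v$gene[i], v$sample[i]] <- TRUE
    if (!is.null(v$loh))
      for (i in which(v$loh %in% TRUE)) loh[v$gene[i], v$sample[i]] <- TRUE
  }
  if (!is.null(loh_calls) && nrow(loh_calls))
    for (i in seq_len(nrow(loh_calls)))
      loh[loh_calls$gene[i], loh_calls$sample[i]] <- TRUE
  if (!is.null(amplification_calls) && nrow(amplification_calls))
    for (i in seq_len(nrow(amplification_calls)))
      amp[amplification_calls$gene[i], amplification_calls$sample[i]] <- TRUE
  nonzero <- rowSums(counts) > 0 | rowSums(loh) > 0 | rowSums(amp) > 0
  structure(list(counts = counts[nonzero, , drop = FALSE],
                 truncating = trunc[nonzero, , drop = FALSE],
                 loh = loh[nonzero, , drop = FALSE],
                 amplified = amp[nonzero, , drop = FALSE],
                 n_skipped = n_skipped),
            class = "gene_sample_matrix")
}

#' @export
print.gene_sample_matrix <- function(x, ...) {
  cat("<gene_sample_matrix> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples (", x$n_skipped,
      " unannotated variants skipped)\n", sep = "")
  invisible(x)
}

#' Recurrence filter: drop genes mutated in a single sample
#'
#' Retains genes carrying filtered mutations in at least `min_samples`
#' distinct samples. Whitelisted genes (established drivers worth keeping
#' for comparison even when mutated once) bypass the threshold.
#'
#' @param matrix a `gene_sample_matrix`.
#' @param min_samples minimum number of mutated samples (inclusive).
#' @param whitelist character vector of genes exempt from the threshold.
#' @return the filtered `gene_sample_matrix`.
#' @export
recurrence_filter <- function(matrix, min_samples = 2,
                              whitelist = character(0)) {
  stopifnot(inherits(matrix, "gene_sample_matrix"))
  n_mut <- rowSums(matrix$counts > 0)
  keep <- n_mut >= min_samples | rownames(matrix$counts) %in% whitelist
  out <- matrix
  for (f in c("counts", "truncating", "loh", "amplified"))
    out[[f]] <- matrix[[f]][keep, , drop = FALSE]
  out
}

#' Per-gene sample co-occurrence
#'
#' 2x2 cross-tabulation of alteration status (mutation count > 0 or
#' amplified) for two genes across samples; mutual exclusivity corresponds
#' to `n_both == 0`.
#'
#' @param matrix a `gene_sample_matrix`.
#' @param gene_a,gene_b gene row names.
#' @return named integer vector `n_both`, `n_a_only`, `n_b_only`,
#'   `n_neither`.
#' @export
cooccurrence <- function(matrix, gene_a, gene_b) {
  stopifnot(inherits(matrix, "gene_sample_matrix"))
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(matrix$counts)) stop("unknown gene: ", g)
  altered <- function(g) matrix$counts[g, ] > 0 | matrix$amplified[g, ]
  a <- altered(gene_a); b <- altered(gene_b)
  c(n_both = sum(a & b), n_a_only = sum(a & !b),
    n_b_only = sum(!a & b), n_neither = sum(!a & !b))
}

#' Proportion of mutant samples showing LOH at a gene
#'
#' Of the samples carrying a filtered mutation in `gene`, the percentage
#' whose mutation is accompanied by loss of heterozygosity (e.g. 2 of 6
#' CDKN1A-mutant cancers -> 33%).
#'
#' @param matrix a `gene_sample_matrix`.
#' @param gene gene row name.
#' @return list(`n_mutant`, `n_loh`, `percent` rounded to integer).
#' @export
gene_loh_proportion <- function(matrix, gene) {
  stopifnot(inherits(matrix, "gene_sample_matrix"))
  if (!gene %in% rownames(matrix$counts)) stop("unknown gene: ", gene)
  mut <- matrix$counts[gene, ] > 0
  loh <- matrix$loh[gene, ] & mut
  list(n_mutant = sum(mut), n_loh = sum(loh),
       percent = if (sum(mut) > 0) round(100 * sum(loh) / sum(mut)) else
         NA_real_)
}

#' Run the full driver-prioritization cascade
#'
#' Convenience composition: functional filter, gene-by-sample matrix
#' construction, recurrence filter.
#'
#' @inheritParams build_gene_sample_matrix
#' @inheritParams recurrence_filter
#' @return a `gene_sample_matrix` of the surviving genes.
#' @export
driver_cascade <- function(variants, amplification_calls = NULL,
                           loh_calls = NULL, min_samples = 2,
                           whitelist = character(0)) {
  kept <- variants[functional_filter(variants), , drop = FALSE]
  m <- build_gene_sample_matrix(kept, amplification_calls, loh_calls)
  recurrence_filter(m, min_samples = min_samples, whitelist = whitelist)
}
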