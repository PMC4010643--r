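# Shared builders and independent oracles for the test suite.

# a tiny two-chromosome genome for interval-level tests
tiny_genome <- function() {
  genome_model(
    chromosomes = data.frame(chrom = c("1", "2"),
                             length = c(10e6, 6e6)),
    centromeres = data.frame(chrom = c("1", "2"),
                             position = c(4e6, 2.5e6)),
    genes = data.frame(
      gene = c("GENEA", "GENEB", "GENEC"),
      chrom = c("1", "1", "2"),
      start = c(100001, 7000001, 500001),
      end = c(150000, 7050000, 550000)))
}

# one-chromosome genome whose single chromosome has n_win 1-Mb windows
flat_genome <- function(n_win = 100) {
  genome_model(
    chromosomes = data.frame(chrom = "1", length = n_win * 1e6),
    centromeres = data.frame(chrom = "1", position = n_win * 1e6 / 2),
    genes = data.frame(gene = "G1", chrom = "1", start = 1e5, end = 2e5))
}

# diploid tiling of a genome for one sample
diploid_segments <- function(genome, sample = "S") {
  data.frame(sample = sample, chrom = genome$chromosomes$chrom,
             start = 1, end = genome$chromosomes$length,
             total_cn = 2L, minor_cn = 1L, loh = FALSE)
}

small_cohort <- function(seed = 42, ...) {
  args <- list(...)
  defaults <- list(n_samples = c(pTa = 2L, pT1 = 2L),
                   mean_snv = c(pTa = 400, pT1 = 1200),
                   prevalences = list(pTa = 1, pT1 = c(1, 0.4)),
                   seed = seed)
  defaults[names(args)] <- args
  generate_cohort(do.call(cohort_config, defaults), mini_genome())
}

# brute-force re-statement of the driver functional filter as a plain
# per-row predicate (independent of the vectorized implementation)
cascade_oracle_keep <- function(v) {
  vapply(seq_len(nrow(v)), function(i) {
    cons <- v$consequence[i]
    if (cons %in% c("stop-gain", "stop-loss", "frameshift", "splice-site"))
      return(TRUE)
    if (cons != "missense") return(FALSE)
    s <- v$sift[i]; p <- v$polyphen2[i]
    !(!is.na(s) && !is.na(p) && s > 0.2 && p < 0.8)
  }, logical(1))
}

# per-base recurrence oracle on a small genome: for every base of a
# chromosome count samples whose event segments cover it
per_base_recurrence <- function(segments, chrom_len, event = "gain") {
  has <- switch(event, gain = segments$total_cn > 2,
                loss = segments$total_cn < 2, loh = segments$loh)
  seg <- segments[has, , drop = FALSE]
  counts <- integer(chrom_len)
  for (sm in unique(seg$sample)) {
    cov <- logical(chrom_len)
    s <- seg[seg$sample == sm, , drop = FALSE]
    for (i in seq_len(nrow(s))) cov[s$start[i]:s$end[i]] <- TRUE
    counts <- counts + cov
  }
  counts
}

# random annotated variant table for cascade equivalence checks
random_annotated_variants <- function(n, seed) {
  set.seed(seed)
  cons <- sample(c("missense", "stop-gain", "stop-loss", "frameshift",
                   "splice-site", "synonymous", "UTR", "intergenic"),
                 n, replace = TRUE)
  sift <- ifelse(runif(n) < 0.2, NA_real_, round(runif(n), 3))
  pp2 <- ifelse(runif(n) < 0.2, NA_real_, round(runif(n), 3))
  data.frame(sample = sample(sprintf("S%02d", 1:6), n, replace = TRUE),
             gene = sample(sprintf("G%d", 1:15), n, replace = TRUE),
             chrom = "1", pos = sample.int(1e6, n), ref = "C", alt = "T",
             consequence = cons, sift = sift, polyphen2 = pp2)
}
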