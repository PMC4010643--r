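#' Read somatic variants from a VCF
#'
#' Parses a VCF 4.2 file (plain or gzipped) with per-sample `DP` and `AD`
#' FORMAT fields into a flat variant table, one row per record per sample,
#' and left-joins an optional annotation table on the exact key
#' (chrom, pos, ref, alt). Records without annotations keep empty
#' annotation fields; records without DP/AD raise a warning and carry NA
#' read counts.
#'
#' @param path VCF file path.
#' @param annotation optional data.frame as produced by
#'   [read_annotation()]: columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `sift`, `polyphen2`, `pop_af`.
#' @return data.frame with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `class` ("SNV"/"indel"), `depth`, `alt_reads`, plus annotation
#'   columns.
#' @export
read_somatic_vcf <- function(path, annotation = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), class = character(0),
                      depth = integer(0), alt_reads = integer(0))
    return(annotate_variants(out, annotation))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    stop("malformed VCF record (non-numeric POS) at record ",
         which(is.na(pos))[1])
  n_sample <- ncol(vcf@gt) - 1L
  if (n_sample < 1) stop("VCF has no sample columns")
  has_dp <- grepl("\\bDP\\b", vcf@gt[, "FORMAT"])
  has_ad <- grepl("\\bAD\\b", vcf@gt[, "FORMAT"])
  if (!all(has_dp & has_ad))
    warning("DP/AD missing for ", sum(!(has_dp & has_ad)),
            " records; read counts unset there")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  ad <- suppressWarnings(vcfR::extract.gt(vcf, "AD"))
  alt_reads <- apply(ad, 2, function(x)
    suppressWarnings(as.integer(vapply(strsplit(x, ","), function(p)
      if (length(p) >= 2) p[2] else NA_character_, character(1)))))
  if (is.null(dim(alt_reads))) alt_reads <- matrix(alt_reads, nrow = nrow(fix))
  present <- !is.na(vcf@gt[, -1, drop = FALSE]) &
    vcf@gt[, -1, drop = FALSE] != "."
  out <- do.call(rbind, lapply(seq_len(n_sample), function(j) {
    d <- data.frame(sample = colnames(vcf@gt)[j + 1L],
                    chrom = fix$CHROM, pos = pos, ref = fix$REF,
                    alt = fix$ALT,
                    class = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1,
                                   "SNV", "indel"),
                    depth = as.integer(dp[, j]),
                    alt_reads = alt_reads[, j],
                    stringsAsFactors = FALSE)
    d[present[, j], , drop = FALSE]
  }))
  rownames(out) <- NULL
  annotate_variants(out, annotation)
}

# left-join the annotation table on (chrom, pos, ref, alt)
annotate_variants <- function(variants, annotation) {
  cols <- c("gene", "consequence", "sift", "polyphen2", "pop_af")
  if (is.null(annotation)) {
    for (cc in cols) if (is.null(variants[[cc]]))
      variants[[cc]] <- rep(if (cc %in% c("sift", "polyphen2", "pop_af"))
        NA_real_ else NA_character_, nrow(variants))
    return(variants)
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  idx <- match(key(variants), key(annotation))
  for (cc in cols)
    variants[[cc]] <- annotation[[cc]][idx]
  variants
}

#' Write somatic variants to a VCF 4.2 file
#'
#' One output file per call; all samples in `variants` become sample
#' columns with FORMAT `DP:AD` (AD as `ref,alt` depths). Records absent in
#' a sample get `.` entries. The file is gzip-compressed (the reader
#' tolerates both).
#'
#' @param variants variant data.frame (as from [generate_cohort()] or
#'   [read_somatic_vcf()]).
#' @param path output path (a `.vcf.gz` suffix is conventional).
#' @return the path, invisibly.
#' @export
write_somatic_vcf <- function(variants, path) {
  v <- variants[order(variants$chrom, variants$pos, variants$ref,
                      variants$alt), ]
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  uk <- !duplicated(key)
  site <- v[uk, c("chrom", "pos", "ref", "alt")]
  fix <- cbind(CHROM = site$chrom, POS = as.character(site$pos),
               ID = ".", REF = site$ref, ALT = site$alt, QUAL = ".",
               FILTER = "PASS", INFO = ".")
  samples <- sort(unique(v$sample))
  gt <- matrix(".", nrow = nrow(site), ncol = length(samples) + 1L,
               dimnames = list(NULL, c("FORMAT", samples)))
  gt[, "FORMAT"] <- "DP:AD"
  row_of <- match(key, key[uk])
  for (i in seq_len(nrow(v))) {
    gt[row_of[i], v$sample[i]] <-
      sprintf("%d:%d,%d", v$depth[i], v$depth[i] - v$alt_reads[i],
              v$alt_reads[i])
  }
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  out <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Read a variant annotation table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#' `sift`, `polyphen2`, `pop_af` (gzip tolerated).
#' @param path file path.
#' @export
read_annotation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Read / write copy-number segment tables
#'
#' TSV with columns `sample`, `chrom`, `start`, `end` (1-based inclusive),
#' `total_cn`, `minor_cn`, `loh_flag` (0/1). The in-memory representation
#' uses a logical `loh` column.
#' @param path file path.
#' @rdname segment_io
#' @export
read_segments <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  d$loh <- as.logical(d$loh_flag)
  d$loh_flag <- NULL
  d
}

#' @param segments segment data.frame.
#' @rdname segment_io
#' @export
write_segments <- function(segments, path) {
  d <- segments
  d$loh_flag <- as.integer(d$loh)
  d$loh <- NULL
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a breakpoint (inter-chromosomal rearrangement) table
#'
#' TSV with columns `sample`, `chromA`, `posA`, `chromB`, `posB`, `score`,
#' `supporting_read_pairs` (BreakDancer-style output).
#' @param path file path.
#' @export
read_breakpoints <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chromA = "character",
                                   chromB = "character"))
}

#' Record-level somatic filters
#'
#' The three call-set filters applied before any downstream analysis, each
#' idempotent and order-preserving:
#' \describe{
#'   \item{`depth_filter`}{keep variants covered by at least `min_depth`
#'     reads (default 10).}
#'   \item{`population_filter`}{remove variants with population allele
#'     frequency strictly greater than `max_af` (default 0.05); missing
#'     frequencies are retained (no evidence to remove).}
#'   \item{`blacklist_filter`}{remove exact (chrom, pos, ref, alt) matches
#'     against a blacklist of recurrent artefact sites compiled from
#'     non-cancer constitutional genomes.}
#' }
#'
#' @param variants variant data.frame.
#' @param min_depth minimum read depth (inclusive).
#' @return the filtered data.frame, original order preserved.
#' @rdname somatic_filters
#' @export
depth_filter <- function(variants, min_depth = 10) {
  if (is.null(variants$depth)) stop("depth column required")
  variants[!is.na(variants$depth) & variants$depth >= min_depth, ,
           drop = FALSE]
}

#' @param max_af maximum tolerated population allele frequency (exclusive).
#' @rdname somatic_filters
#' @export
population_filter <- function(variants, max_af = 0.05) {
  af <- variants$pop_af
  if (is.null(af)) return(variants)
  variants[is.na(af) | af <= max_af, , drop = FALSE]
}

#' @param blacklist data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @rdname somatic_filters
#' @export
blacklist_filter <- function(variants, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(variants)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  variants[!(key(variants) %in% key(blacklist)), , drop = FALSE]
}

#' Filter rearrangement breakpoints
#'
#' Retains records with confidence score at least `min_score` (the caller's
#' scores cap at 99, so the default keeps only top-confidence calls), at
#' least `min_pairs` supporting read pairs, and — when `require_in_gene` —
#' at least one anchor falling inside a catalogued gene.
#'
#' @param records breakpoint data.frame (see [read_breakpoints()]).
#' @param genome a `genome_model` supplying the gene catalog.
#' @param min_score minimum score (inclusive).
#' @param min_pairs minimum supporting read pairs (inclusive).
#' @param require_in_gene require an in-gene anchor.
#' @return filtered data.frame, order preserved.
#' @export
filter_breakpoints <- function(records, genome, min_score = 99,
                               min_pairs = 10, require_in_gene = TRUE) {
  keep <- records$score >= min_score &
    records$supporting_read_pairs >= min_pairs
  if (require_in_gene) {
    genes <- genome$genes
    in_gene_a <- overlaps_any(records$chromA, records$posA, records$posA,
                              data.frame(chrom = genes$chrom,
                                         start = genes$start,
                                         end = genes$end))
    in_gene_b <- overlaps_any(records$chromB, records$posB, records$posB,
                              data.frame(chrom = genes$chrom,
                                         start = genes$start,
                                         end = genes$end))
    keep <- keep & (in_gene_a | in_gene_b)
  }
  records[keep, , drop = FALSE]
}
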