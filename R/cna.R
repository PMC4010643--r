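#' Fraction of the genome altered by copy number change or LOH
#'
#' The per cent of genome length covered by segments whose state departs
#' from diploid heterozygous: total copy number different from 2, or LOH
#' (copy-neutral LOH counts as altered). Requires the segments of one
#' sample to tile the genome exactly; gaps are an error.
#'
#' @param segments one sample's segment data.frame (`chrom`, `start`,
#'   `end`, `total_cn`, `loh`).
#' @param genome a `genome_model`.
#' @return percentage in [0, 100].
#' @export
fraction_genome_altered <- function(segments, genome) {
  .check_tiling(segments, genome)
  altered <- segments$total_cn != 2 | segments$loh
  100 * sum(as.numeric(segments$end - segments$start + 1)[altered]) /
    genome_length(genome)
}

.check_tiling <- function(segments, genome) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  gaps <- character(0)
  for (i in seq_len(nrow(genome$chromosomes))) {
    cc <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    seg <- segments[segments$chrom == cc, , drop = FALSE]
    seg <- seg[order(seg$start), ]
    if (nrow(seg) == 0) { gaps <- c(gaps, paste0(cc, ":1-", fmt(len))); next }
    if (seg$start[1] != 1)
      gaps <- c(gaps, paste0(cc, ":1-", fmt(seg$start[1] - 1)))
    inner <- which(seg$start[-1] != seg$end[-nrow(seg)] + 1)
    for (j in inner)
      gaps <- c(gaps, paste0(cc, ":", fmt(seg$end[j] + 1), "-",
                             fmt(seg$start[j + 1] - 1)))
    if (seg$end[nrow(seg)] != len)
      gaps <- c(gaps, paste0(cc, ":", fmt(seg$end[nrow(seg)] + 1), "-",
                             fmt(len)))
  }
  if (length(gaps))
    stop("segments do not tile the genome; gaps: ",
         paste(gaps, collapse = ", "))
  invisible(TRUE)
}

#' Scan chromosome arms for chromothripsis
#'
#' A chromosome arm is flagged when its segmentation shows at least
#' `min_transitions` changes of the joint (total copy number, LOH) state
#' between adjacent segments. Segments straddling the centromere are split
#' there before counting, so each boundary is attributed to a single arm.
#' The transition count equals the number of distinct joint-state runs on
#' the arm minus one.
#'
#' @param segments segment data.frame, possibly multi-sample (needs a
#'   `sample` column; a single sample's table without one is tolerated).
#' @param genome a `genome_model` with centromere positions.
#' @param min_transitions flagging threshold (default 10).
#' @return data.frame: `sample`, `chrom`, `arm`, `n_transitions`,
#'   `flagged`.
#' @export
chromothripsis_scan <- function(segments, genome, min_transitions = 10) {
  if (is.null(segments$sample)) segments$sample <- "sample"
  out <- list()
  for (sm in unique(segments$sample)) {
    sseg <- segments[segments$sample == sm, , drop = FALSE]
    for (i in seq_len(nrow(genome$chromosomes))) {
      cc <- genome$chromosomes$chrom[i]
      cen <- genome$centromeres$position[
        match(cc, genome$centromeres$chrom)]
      seg <- sseg[sseg$chrom == cc, , drop = FALSE]
      seg <- seg[order(seg$start), ]
      for (arm in c("p", "q")) {
        lo <- if (arm == "p") 1 else cen + 1
        hi <- if (arm == "p") cen else genome$chromosomes$length[i]
        a <- seg[seg$end >= lo & seg$start <= hi, , drop = FALSE]
        n_tr <- if (nrow(a) < 2) 0L else {
          state <- paste(a$total_cn, a$loh)
          sum(state[-1] != state[-length(state)])
        }
        out[[length(out) + 1]] <- data.frame(
          sample = sm, chrom = cc, arm = arm, n_transitions = n_tr,
          flagged = n_tr >= min_transitions)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recurrently altered regions across a cohort
#'
#' Sweeps the union of all segment boundaries and, for each elementary
#' interval, counts the samples carrying the event type (`gain`: total
#' copy number > 2; `loss`: < 2; `loh`). Adjacent intervals with the same
#' count are merged; intervals reaching `min_samples` are reported.
#'
#' @param segments multi-sample segment data.frame (with `sample`).
#' @param min_samples recurrence threshold (inclusive, default 6).
#' @param event one of `"gain"`, `"loss"`, `"loh"`.
#' @return data.frame `chrom`, `start`, `end`, `n_samples`.
#' @export
recurrent_regions <- function(segments, min_samples = 6,
                              event = c("gain", "loss", "loh")) {
  event <- match.arg(event)
  has <- switch(event,
                gain = segments$total_cn > 2,
                loss = segments$total_cn < 2,
                loh = segments$loh)
  seg <- segments[has, , drop = FALSE]
  out <- list()
  for (cc in unique(seg$chrom)) {
    s <- seg[seg$chrom == cc, , drop = FALSE]
    bounds <- sort(unique(c(s$start, s$end + 1)))
    if (length(bounds) < 2) next
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1
    counts <- vapply(seq_along(starts), function(j) {
      cover <- s$start <= starts[j] & s$end >= ends[j]
      length(unique(s$sample[cover]))
    }, integer(1))
    keep <- counts >= min_samples
    if (!any(keep)) next
    # merge adjacent kept intervals with identical counts
    runs <- rle(paste(keep, counts))
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    for (r in seq_along(runs$lengths)) {
      j <- idx_start[r]
      if (!keep[j]) next
      # contiguity check: merged run must be gap-free
      lo <- j
      while (lo <= idx_end[r]) {
        hi <- lo
        while (hi < idx_end[r] && starts[hi + 1] == ends[hi] + 1) hi <- hi + 1
        out[[length(out) + 1]] <- data.frame(
          chrom = cc, start = starts[lo], end = ends[hi],
          n_samples = counts[j])
        lo <- hi + 1
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_samples = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes hit by homozygous deletion
#'
#' Reports every (sample, gene) pair where a total-copy-number-zero
#' segment overlaps the gene by at least one bp.
#'
#' @param segments multi-sample segment data.frame.
#' @param genome a `genome_model` supplying the gene catalog.
#' @return data.frame `sample`, `gene`, `chrom`.
#' @export
homozygous_deletions <- function(segments, genome) {
  hd <- segments[segments$total_cn == 0, , drop = FALSE]
  out <- list()
  genes <- genome$genes
  for (i in seq_len(nrow(hd))) {
    hit <- genes$chrom == hd$chrom[i] & genes$start <= hd$end[i] &
      genes$end >= hd$start[i]
    for (g in which(hit))
      out[[length(out) + 1]] <- data.frame(
        sample = hd$sample[i] %||% "sample", gene = genes$gene[g],
        chrom = genes$chrom[g])
  }
  if (!length(out))
    return(data.frame(sample = character(0), gene = character(0),
                      chrom = character(0)))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Expected B-allele fraction of a germline heterozygote
#'
#' At a locus of total copy number `total_cn` with the tracked allele on
#' `allele_cn` copies, in a tumour of purity `purity` (normal cells
#' contribute one copy of each allele):
#' \deqn{BAF = (t \cdot a + (1 - t)) / (t \cdot c + 2 (1 - t)).}
#' With purity 1 this reduces to `allele_cn / total_cn` — e.g. 2/3 for the
#' major allele of a 2:1 gain, 7/8 for a 7:1 high-level amplification.
#'
#' @param total_cn total copy number at the locus.
#' @param allele_cn copies carrying the tracked allele.
#' @param purity tumour cell fraction in (0, 1].
#' @return expected BAF in [0, 1].
#' @export
expected_het_baf <- function(total_cn, allele_cn, purity = 1) {
  stopifnot(all(allele_cn <= total_cn), all(purity > 0 & purity <= 1))
  (purity * allele_cn + (1 - purity)) /
    (purity * total_cn + 2 * (1 - purity))
}

#' Allele-fraction profile of an amplicon
#'
#' Grows the amplicon region as the maximal contiguous run of segments
#' with total copy number at least `cn_threshold` containing the anchor
#' gene, then profiles every germline heterozygote and somatic variant in
#' the region: positions, observed tumour BAF/VAF, constitutional BAF,
#' and the copy-number track. The allelic asymmetry statistic is the mean
#' of |tumour BAF - 0.5| over germline heterozygotes (0 for a balanced
#' region, 0.375 for a fully pure 7:1 amplification).
#'
#' @param variants one sample's somatic variant data.frame.
#' @param germline_hets one sample's heterozygote table (`chrom`, `pos`,
#'   `tumour_baf`, `constitutional_baf`).
#' @param segments one sample's segments.
#' @param genome a `genome_model`.
#' @param anchor_gene gene the amplicon must contain.
#' @param cn_threshold minimal amplified copy number (default 3).
#' @return object of class `amplicon_profile`: list with `region`,
#'   `rows` (per-variant profile), `cn_track`, `asymmetry`, `empty`,
#'   `reason`.
#' @export
amplicon_profile <- function(variants, germline_hets, segments, genome,
                             anchor_gene, cn_threshold = 3) {
  gi <- genome$genes[genome$genes$gene == anchor_gene, ]
  if (nrow(gi) != 1) stop("unknown anchor gene: ", anchor_gene)
  seg <- segments[segments$chrom == gi$chrom, , drop = FALSE]
  seg <- seg[order(seg$start), ]
  over <- seg$start <= gi$end & seg$end >= gi$start
  amp_over <- over & seg$total_cn >= cn_threshold
  if (!any(amp_over)) {
    return(structure(list(region = NULL, rows = NULL, cn_track = NULL,
                          asymmetry = NA_real_, empty = TRUE,
                          reason = paste0("no segment with total_cn >= ",
                                          cn_threshold, " overlaps ",
                                          anchor_gene)),
                     class = "amplicon_profile"))
  }
  amp <- seg$total_cn >= cn_threshold
  i0 <- which(amp_over)[1]
  lo <- i0; hi <- i0
  while (lo > 1 && amp[lo - 1] && seg$start[lo] == seg$end[lo - 1] + 1)
    lo <- lo - 1
  while (hi < nrow(seg) && amp[hi + 1] && seg$end[hi] + 1 == seg$start[hi + 1])
    hi <- hi + 1
  region <- list(chrom = gi$chrom, start = seg$start[lo], end = seg$end[hi])
  in_region <- function(d) d$chrom == region$chrom &
    d$pos >= region$start & d$pos <= region$end
  hets <- germline_hets[in_region(germline_hets), , drop = FALSE]
  som <- variants[in_region(variants), , drop = FALSE]
  rows <- rbind(
    if (nrow(hets)) data.frame(pos = hets$pos, class = "germline-het",
                               tumour_baf = hets$tumour_baf,
                               constitutional_baf = hets$constitutional_baf),
    if (nrow(som)) data.frame(pos = som$pos, class = "somatic",
                              tumour_baf = ifelse(som$depth > 0,
                                                  som$alt_reads / som$depth,
                                                  NA_real_),
                              constitutional_baf = 0))
  asym <- if (nrow(hets) && any(!is.na(hets$tumour_baf)))
    mean(abs(hets$tumour_baf - 0.5), na.rm = TRUE) else NA_real_
  structure(list(region = region,
                 rows = rows[order(rows$pos), , drop = FALSE],
                 cn_track = seg[lo:hi, c("chrom", "start", "end",
                                         "total_cn", "minor_cn")],
                 asymmetry = asym, empty = FALSE,
                 reason = if (is.na(asym)) "no heterozygous sites in region"
                 else NA_character_),
            class = "amplicon_profile")
}

#' @export
print.amplicon_profile <- function(x, ...) {
  if (x$empty) {
    cat("<amplicon_profile> empty:", x$reason, "\n")
  } else {
    cat("<amplicon_profile> ", x$region$chrom, ":", x$region$start, "-",
        x$region$end, ", ", nrow(x$rows), " profiled sites, asymmetry ",
        round(x$asymmetry, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Mutation-density excess within an amplicon
#'
#' Observed/expected per-bp density ratios for SNVs and indels inside a
#' region, with the expectation taken from the rest of the genome. A
#' copy-number-adjusted ratio (expectation scaled by mean total copy /
#' 2) is reported alongside, so an excess that survives adjustment cannot
#' be accounted for by the increased copy number alone.
#'
#' @param variants one sample's variants (`chrom`, `pos`, `class`).
#' @param region list(`chrom`, `start`, `end`).
#' @param segments one sample's segments (for the region's mean copy
#'   number).
#' @param genome a `genome_model`.
#' @return list(`snv_ratio`, `indel_ratio`, `mean_cn`,
#'   `snv_ratio_cn_adjusted`, `indel_ratio_cn_adjusted`).
#' @export
amplicon_mutation_excess <- function(variants, region, segments, genome) {
  width <- region$end - region$start + 1
  if (width <= 0) stop("zero-length region")
  inside <- variants$chrom == region$chrom &
    variants$pos >= region$start & variants$pos <= region$end
  g_len <- genome_length(genome) - width
  dens <- function(cls) {
    n_in <- sum(inside & variants$class == cls)
    n_out <- sum(!inside & variants$class == cls)
    bg <- n_out / g_len
    if (bg == 0) return(ifelse(n_in > 0, Inf, NA_real_))
    (n_in / width) / bg
  }
  seg <- segments[segments$chrom == region$chrom, , drop = FALSE]
  ov_s <- pmax(seg$start, region$start); ov_e <- pmin(seg$end, region$end)
  w <- pmax(ov_e - ov_s + 1, 0)
  mean_cn <- if (sum(w) > 0) sum(w * seg$total_cn) / sum(w) else NA_real_
  snv_r <- dens("SNV"); ind_r <- dens("indel")
  list(snv_ratio = snv_r, indel_ratio = ind_r, mean_cn = mean_cn,
       snv_ratio_cn_adjusted = snv_r / (mean_cn / 2),
       indel_ratio_cn_adjusted = ind_r / (mean_cn / 2))
}
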