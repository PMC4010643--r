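#' Tile the genome into fixed windows and count mutations
#'
#' Non-overlapping windows of `window_size` bp tile each chromosome (the
#' last window of a chromosome may be shorter); SNVs and indels are
#' counted separately per window. Window `i` on a chromosome covers
#' 1-based positions `(i-1)*w + 1` to `i*w`, so a variant at position
#' `w + 1` falls in the second window.
#'
#' @param variants variant data.frame with `chrom`, `pos` and optionally
#'   `class` ("SNV"/"indel"; all rows counted as SNV when absent).
#' @param genome a `genome_model`.
#' @param window_size window width in bp (default 1 Mb).
#' @return data.frame of window records: `chrom`, `window`, `start`,
#'   `end`, `width`, `snv_count`, `indel_count`.
#' @export
window_counts <- function(variants, genome, window_size = 1e6) {
  stopifnot(window_size >= 1)
  lens <- chrom_lengths(genome)
  bad <- !(variants$chrom %in% names(lens)) |
    variants$pos < 1 | variants$pos > lens[variants$chrom]
  if (any(bad))
    stop("variant outside genome bounds: ",
         paste0(variants$chrom[which(bad)[1]], ":",
                variants$pos[which(bad)[1]]))
  cls <- if (is.null(variants$class)) rep("SNV", nrow(variants)) else
    variants$class
  out <- lapply(names(lens), function(cc) {
    len <- lens[[cc]]
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1) * window_size + 1
    end <- pmin(seq_len(n_win) * window_size, len)
    sel <- variants$chrom == cc
    widx <- (variants$pos[sel] - 1) %/% window_size + 1
    f <- factor(widx, levels = seq_len(n_win))
    data.frame(chrom = cc, window = seq_len(n_win), start = start,
               end = end, width = end - start + 1,
               snv_count = as.integer(table(f[cls[sel] == "SNV"])),
               indel_count = as.integer(table(f[cls[sel] != "SNV"])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call mutation hotspot windows
#'
#' Tests each window's total mutation count against the genome-wide mean
#' density with a one-sided Poisson upper tail
#' (\eqn{P(X \ge n)} at \eqn{\lambda =} genome-wide rate x window width,
#' so short terminal windows get a length-adjusted expectation), applies
#' Benjamini-Hochberg correction across windows, and flags windows with
#' q-value at most `alpha`.
#'
#' @param records window data.frame from [window_counts()].
#' @param alpha false-discovery threshold.
#' @return the records with `expected`, `p_value`, `q_value` and
#'   `hotspot` columns appended.
#' @export
call_hotspots <- function(records, alpha = 0.05) {
  if (nrow(records) == 0) stop("at least one window required")
  n <- records$snv_count + records$indel_count
  total <- sum(n)
  if (total == 0) {
    records$expected <- 0; records$p_value <- 1
    records$q_value <- 1; records$hotspot <- FALSE
    return(records)
  }
  rate <- total / sum(records$width)
  lambda <- rate * records$width
  p <- stats::ppois(n - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  records$expected <- lambda
  records$p_value <- p
  records$q_value <- q
  records$hotspot <- q <= alpha
  records
}

#' Annotate hotspot windows with mundane explanations
#'
#' Flags windows whose elevated counts are plausibly explained by local
#' copy number (`cn_explained`: length-weighted mean total copy number
#' over the window exceeds `cn_threshold`) and windows near centromeres or
#' chromosome ends (`near_centromere_or_telomere`: overlap with a
#' `margin`-bp window around either landmark), where mapping artefacts
#' concentrate.
#'
#' @param records window data.frame (one sample's scan).
#' @param segments that sample's copy-number segments.
#' @param genome a `genome_model`.
#' @param cn_threshold mean copy number above which a window counts as
#'   CN-explained.
#' @param margin bp around centromeres/telomeres.
#' @return records with `mean_cn`, `cn_explained`,
#'   `near_centromere_or_telomere` columns appended.
#' @export
annotate_explanations <- function(records, segments, genome,
                                  cn_threshold = 2.5, margin = 2e6) {
  lens <- chrom_lengths(genome)
  mean_cn <- numeric(nrow(records))
  near <- logical(nrow(records))
  for (cc in unique(records$chrom)) {
    sel <- which(records$chrom == cc)
    seg <- segments[segments$chrom == cc, , drop = FALSE]
    for (i in sel) {
      ws <- records$start[i]; we <- records$end[i]
      ov_s <- pmax(seg$start, ws); ov_e <- pmin(seg$end, we)
      w <- pmax(ov_e - ov_s + 1, 0)
      mean_cn[i] <- if (sum(w) > 0) sum(w * seg$total_cn) / sum(w) else
        NA_real_
    }
    cen <- genome$centromeres$position[
      match(cc, genome$centromeres$chrom)]
    len <- lens[[cc]]
    lm <- cbind(lo = c(1, cen - margin, len - margin + 1),
                hi = c(margin, cen + margin, len))
    for (i in sel)
      near[i] <- any(records$start[i] <= lm[, "hi"] &
                       records$end[i] >= lm[, "lo"])
  }
  records$mean_cn <- mean_cn
  records$cn_explained <- !is.na(mean_cn) & mean_cn > cn_threshold
  records$near_centromere_or_telomere <- near
  records
}
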