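#' Cohort simulation configuration
#'
#' Defines the statistical structure of a simulated tumour/normal cohort:
#' per-stage sample counts and mean somatic burden, the six-class
#' substitution spectrum, clonal structure (cellular prevalences), purity,
#' sequencing depth, and segment-level copy-number event rates. Defaults
#' emulate a 14-tumour whole-genome discovery cohort: four non-invasive
#' (pTa) tumours with ~35,000 SNVs each and ten invasive (pT1/pT2) tumours
#' with ~115,000 SNVs each at ~80x depth, an indel:SNV ratio of 0.22, and a
#' spectrum dominated by C:G>T:A (33%) followed by T:A>C:G and C:G>G:C.
#' Invasive tumours carry a subclone at prevalence 0.4 next to the founding
#' clone; non-invasive tumours are monoclonal.
#'
#' @param n_samples named integer vector: samples per stage group.
#' @param mean_snv named numeric vector: mean somatic SNV count per group.
#' @param indel_ratio expected indels per SNV (indel counts are drawn
#'   Poisson with mean `indel_ratio * n_snv`, hence correlated with SNVs).
#' @param spectrum probabilities over the six substitution classes, in the
#'   order of [spectrum_classes()]; must sum to 1.
#' @param prevalences list of numeric vectors, one per stage group: the
#'   cellular prevalences of the clones present in samples of that group.
#'   All values in (0, 1].
#' @param purity tumour cell fraction per sample group (or single value);
#'   in (0, 1].
#' @param depth_mean mean sequencing depth (per-site depth is Poisson).
#' @param seg_rates named numeric vector of per-segment state
#'   probabilities: `gain`, `loss`, `cnloh`, `homdel` (remainder diploid).
#' @param segs_per_chrom expected number of extra breakpoints per
#'   chromosome (segment count is 1 + Poisson(segs_per_chrom)).
#' @param het_density expected germline heterozygous SNPs per bp (used for
#'   B-allele-fraction profiling).
#' @param amplicon optional list(`gene`, `samples`, `levels`, `minor`)
#'   describing a focal amplification to inject: a run of segments at total
#'   copy `levels` (e.g. `c(8, 3)`) with minor copy `minor` around the
#'   anchor gene in the named samples.
#' @param chromothripsis optional list(`sample`, `chrom`, `arm`,
#'   `n_transitions`) describing a shattered arm to inject.
#' @param seed mandatory integer seed; fixed seed gives byte-identical
#'   output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = c(pTa = 4L, pT1 = 5L, pT2 = 5L),
                          mean_snv = c(pTa = 35000, pT1 = 115000, pT2 = 115000),
                          indel_ratio = 0.22,
                          spectrum = c(0.33, 0.15, 0.17, 0.20, 0.09, 0.06),
                          prevalences = list(pTa = 1.0, pT1 = c(1.0, 0.4),
                                             pT2 = c(1.0, 0.4)),
                          purity = c(pTa = 0.8, pT1 = 0.8, pT2 = 0.8),
                          depth_mean = 80,
                          seg_rates = c(gain = 0.15, loss = 0.15,
                                        cnloh = 0.05, homdel = 0.01),
                          segs_per_chrom = 2,
                          het_density = 1 / 100000,
                          amplicon = NULL,
                          chromothripsis = NULL,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory")
  groups <- names(n_samples)
  if (is.null(groups)) stop("n_samples must be a named vector of stage groups")
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != 6 || abs(sum(spectrum) - 1) > 1e-9)
    stop("spectrum must be 6 probabilities summing to 1")
  for (p in unlist(prevalences))
    if (p <= 0 || p > 1) stop("prevalences must lie in (0, 1]")
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (sum(seg_rates) > 1) stop("segment event rates must sum to <= 1")
  structure(list(n_samples = n_samples, mean_snv = mean_snv,
                 indel_ratio = indel_ratio, spectrum = spectrum,
                 prevalences = prevalences, purity = purity,
                 depth_mean = depth_mean, seg_rates = seg_rates,
                 segs_per_chrom = segs_per_chrom, het_density = het_density,
                 amplicon = amplicon, chromothripsis = chromothripsis,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# expand a per-group parameter to one value per group name, tolerating a
# single unnamed value
.per_group <- function(x, groups) {
  if (length(x) == 1 && is.null(names(x))) return(stats::setNames(rep(x, length(groups)), groups))
  if (!all(groups %in% names(x))) stop("missing per-group parameter for some stage group")
  x[groups]
}

# segments for one sample: tile every chromosome exactly once, assigning
# (total_cn, minor_cn) per segment from the configured event rates
.simulate_segments <- function(config, genome, sample_id) {
  rates <- config$seg_rates
  states <- data.frame(
    state = c("diploid", "gain", "loss", "cnloh", "homdel"),
    total_cn = c(2L, 3L, 1L, 2L, 0L),
    minor_cn = c(1L, 1L, 0L, 0L, 0L))
  probs <- c(1 - sum(rates), rates[["gain"]], rates[["loss"]],
             rates[["cnloh"]], rates[["homdel"]])
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    chrom <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    k <- 1L + stats::rpois(1, config$segs_per_chrom)
    cuts <- sort(sample.int(len - 1L, min(k - 1L, len - 1L)))
    start <- c(1L, cuts + 1L)
    end <- c(cuts, len)
    st <- sample(nrow(states), length(start), replace = TRUE, prob = probs)
    data.frame(sample = sample_id, chrom = chrom, start = start, end = end,
               total_cn = states$total_cn[st], minor_cn = states$minor_cn[st])
  })
  seg <- do.call(rbind, out)
  seg$loh <- seg$minor_cn == 0L & seg$total_cn >= 1L
  seg
}

# total copy number of the covering segment for each (chrom, pos) of one sample
.segment_cn_at <- function(segments, chrom, pos) {
  cn <- integer(length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    seg <- segments[segments$chrom == cc, ]
    seg <- seg[order(seg$start), ]
    idx <- findInterval(pos[sel], seg$start)
    cn[sel] <- seg$total_cn[idx]
  }
  cn
}

# draw substitution ref/alt pairs for a vector of class indices (1..6),
# flipping to the purine-reference representation with probability 1/2
.draw_substitutions <- function(class_idx) {
  # pyrimidine representation per class, matching spectrum_classes()
  pyr_ref <- c("C", "C", "C", "T", "T", "T")[class_idx]
  pyr_alt <- c("T", "A", "G", "C", "A", "G")[class_idx]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- stats::runif(length(class_idx)) < 0.5
  ref <- ifelse(flip, comp[pyr_ref], pyr_ref)
  alt <- ifelse(flip, comp[pyr_alt], pyr_alt)
  list(ref = unname(ref), alt = unname(alt))
}

#' Simulate a tumour/normal somatic call cohort
#'
#' Draws, for every sample: a somatic SNV count (Poisson around its stage
#' group's mean), an indel count (Poisson, `indel_ratio` x SNV count, hence
#' correlated), uniform genomic positions, substitution classes from the
#' configured spectrum, a clone label from the sample's prevalence vector,
#' and per-site read counts. The expected variant allele fraction of a
#' mutation on `m` copies at a locus of total copy number `c`, in a clone
#' of cellular prevalence `f` and a sample of purity `t`, is
#' \deqn{VAF = t f m / (t c + 2 (1 - t)),}
#' depth is Poisson(`depth_mean`) and alt reads Binomial(depth, VAF).
#' Copy-number segments tile each chromosome exactly once; optional focal
#' amplicons and chromothripsis arms are injected afterwards. Germline
#' heterozygous SNPs are seeded for B-allele-fraction profiling.
#'
#' @param config a [cohort_config()].
#' @param genome a [genome_model()]; default [mini_genome()].
#' @return list with elements `variants`, `segments`, `samples`,
#'   `germline_hets` (data.frames) and `truth` (per-variant clone labels
#'   and prevalences, for recovery tests).
#' @export
generate_cohort <- function(config, genome = mini_genome()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- names(config$n_samples)
  purity <- .per_group(config$purity, groups)
  mean_snv <- .per_group(config$mean_snv, groups)
  if (!is.null(config$amplicon) &&
      !config$amplicon$gene %in% genome$genes$gene)
    stop("amplicon anchor gene not in genome catalog")

  samples <- data.frame(
    sample = character(0), stage = character(0), purity = numeric(0))
  sid <- 0L
  for (g in groups) {
    for (k in seq_len(config$n_samples[[g]])) {
      sid <- sid + 1L
      samples <- rbind(samples, data.frame(
        sample = sprintf("S%02d", sid), stage = g, purity = purity[[g]]))
    }
  }
  samples$grade <- ifelse(samples$stage == "pTa", "G1-2", "G3")
  samples$dna_index <- 1.0

  chrlen <- chrom_lengths(genome)
  glen <- genome_length(genome)

  seg_list <- list(); var_list <- list(); het_list <- list()
  for (i in seq_len(nrow(samples))) {
    sm <- samples$sample[i]; g <- samples$stage[i]; t <- samples$purity[i]
    seg <- .simulate_segments(config, genome, sm)
    if (!is.null(config$amplicon) &&
        (is.null(config$amplicon$samples) || sm %in% config$amplicon$samples))
      seg <- inject_amplicon(seg, genome, config$amplicon$gene,
                             levels = config$amplicon$levels,
                             minor = config$amplicon$minor %||% 1L)
    if (!is.null(config$chromothripsis) && sm %in% config$chromothripsis$sample)
      seg <- inject_chromothripsis(seg, genome, config$chromothripsis$chrom,
                                   config$chromothripsis$arm,
                                   config$chromothripsis$n_transitions)
    seg_list[[i]] <- seg

    prev <- config$prevalences[[g]]
    n_snv <- stats::rpois(1, mean_snv[[g]])
    n_ind <- stats::rpois(1, config$indel_ratio * n_snv)
    n <- n_snv + n_ind
    chrom <- sample(names(chrlen), n, replace = TRUE, prob = chrlen / glen)
    pos <- floor(stats::runif(n) * chrlen[chrom]) + 1
    is_snv <- c(rep(TRUE, n_snv), rep(FALSE, n_ind))
    cls <- sample.int(6L, n, replace = TRUE, prob = config$spectrum)
    sub <- .draw_substitutions(cls)
    ref <- ifelse(is_snv, sub$ref, "AC")
    alt <- ifelse(is_snv, sub$alt, "A")
    clone <- sample.int(length(prev), n, replace = TRUE)
    f <- prev[clone]
    cn <- .segment_cn_at(seg, chrom, pos)
    mult <- 1L
    vaf <- ifelse(cn == 0, 0, t * f * mult / (t * cn + 2 * (1 - t)))
    vaf <- pmin(vaf, 1)
    depth <- stats::rpois(n, config$depth_mean)
    alt_reads <- stats::rbinom(n, depth, vaf)
    var_list[[i]] <- data.frame(
      sample = rep(sm, n), chrom = chrom, pos = pos, ref = ref, alt = alt,
      class = ifelse(is_snv, "SNV", "indel"),
      depth = depth, alt_reads = alt_reads,
      clone = clone, prevalence = f, multiplicity = mult,
      total_cn = cn, purity = t, row.names = NULL)

    n_het <- stats::rpois(1, config$het_density * glen)
    hchrom <- sample(names(chrlen), n_het, replace = TRUE, prob = chrlen / glen)
    hpos <- floor(stats::runif(n_het) * chrlen[hchrom]) + 1
    hcn_idx <- .segment_state_at(seg, hchrom, hpos)
    hcn <- seg$total_cn[hcn_idx]; hminor <- seg$minor_cn[hcn_idx]
    b_is_major <- stats::runif(n_het) < 0.5
    ballele <- ifelse(b_is_major, hcn - hminor, hminor)
    baf <- ifelse(hcn == 0 & t == 1, 0.5,
                  (t * ballele + (1 - t) * 1) / (t * hcn + (1 - t) * 2))
    hdepth <- stats::rpois(n_het, config$depth_mean)
    halt <- stats::rbinom(n_het, hdepth, pmin(pmax(baf, 0), 1))
    het_list[[i]] <- data.frame(
      sample = rep(sm, n_het), chrom = hchrom, pos = hpos,
      depth = hdepth, alt_reads = halt,
      tumour_baf = ifelse(hdepth > 0, halt / hdepth, NA_real_),
      constitutional_baf = rep(0.5, n_het), row.names = NULL)
  }
  variants <- do.call(rbind, var_list)
  segments <- do.call(rbind, seg_list)
  hets <- do.call(rbind, het_list)
  rownames(variants) <- rownames(segments) <- rownames(hets) <- NULL
  truth <- variants[, c("sample", "chrom", "pos", "clone", "prevalence")]
  list(variants = variants, segments = segments, samples = samples,
       germline_hets = hets, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# row index of the covering segment (within one sample's segment table)
.segment_state_at <- function(segments, chrom, pos) {
  idx <- integer(length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    rows <- which(segments$chrom == cc)
    rows <- rows[order(segments$start[rows])]
    idx[sel] <- rows[findInterval(pos[sel], segments$start[rows])]
  }
  idx
}

#' Inject a focal amplification around an anchor gene
#'
#' Replaces the segments of one sample overlapping a window around the
#' anchor gene with a run of segments at the given total copy-number
#' levels (minor copy `minor`), producing the intercalated high/low
#' amplicon structure seen at recurrent oncogene amplicons.
#'
#' @param segments one sample's segment data.frame.
#' @param genome a `genome_model` containing the anchor gene.
#' @param gene anchor gene name.
#' @param levels total copy number per amplicon sub-segment (anchor gene
#'   sits in the first level).
#' @param minor minor-allele copy number within the amplicon.
#' @param pad bp added either side of the gene per sub-segment.
#' @return modified segment data.frame, still tiling every chromosome.
#' @export
inject_amplicon <- function(segments, genome, gene, levels = c(8L, 3L),
                            minor = 1L, pad = 200000L) {
  gi <- genome$genes[genome$genes$gene == gene, ]
  if (nrow(gi) != 1) stop("amplicon anchor gene not in genome catalog")
  chrom <- gi$chrom
  len <- chrom_lengths(genome)[[chrom]]
  a_start <- max(1L, gi$start - pad)
  widths <- rep(ceiling((gi$end + pad * length(levels) - a_start + 1) /
                          length(levels)), length(levels))
  bounds <- a_start + c(0L, cumsum(widths))
  a_end <- min(len, bounds[length(bounds)] - 1L)
  keep <- segments$chrom != chrom
  chr_seg <- segments[segments$chrom == chrom, ]
  chr_seg <- chr_seg[order(chr_seg$start), ]
  out <- list()
  for (j in seq_len(nrow(chr_seg))) {
    s <- chr_seg[j, ]
    if (s$end < a_start || s$start > a_end) { out[[length(out) + 1]] <- s; next }
    if (s$start < a_start) { left <- s; left$end <- a_start - 1L; out[[length(out) + 1]] <- left }
    if (s$end > a_end) { right <- s; right$start <- a_end + 1L; out[[length(out) + 1]] <- right }
  }
  for (j in seq_along(levels)) {
    amp <- chr_seg[1, ]
    amp$start <- bounds[j]
    amp$end <- min(a_end, bounds[j + 1] - 1L)
    amp$total_cn <- as.integer(levels[j])
    amp$minor_cn <- as.integer(min(minor, levels[j] %/% 2L))
    amp$loh <- amp$minor_cn == 0L & amp$total_cn >= 1L
    out[[length(out) + 1]] <- amp
  }
  res <- rbind(segments[keep, ], do.call(rbind, out))
  res <- res[order(match(res$chrom, genome$chromosomes$chrom), res$start), ]
  rownames(res) <- NULL
  res
}

#' Inject a chromothripsis arm
#'
#' Rebuilds one chromosome arm of a sample's segmentation as
#' `n_transitions + 1` equal segments whose joint (total copy number, LOH)
#' state changes at every internal boundary, giving exactly
#' `n_transitions` state transitions on the arm. The rest of the genome is
#' untouched.
#'
#' @param segments one sample's segment data.frame.
#' @param genome a `genome_model` (for the centromere position).
#' @param chrom chromosome name.
#' @param arm `"p"` or `"q"`.
#' @param n_transitions number of joint-state changes to create (>= 0).
#' @return modified segment data.frame.
#' @export
inject_chromothripsis <- function(segments, genome, chrom, arm = "q",
                                  n_transitions = 12L) {
  stopifnot(arm %in% c("p", "q"), n_transitions >= 0)
  ci <- match(chrom, genome$chromosomes$chrom)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  cen <- genome$centromeres$position[match(chrom, genome$centromeres$chrom)]
  len <- genome$chromosomes$length[ci]
  lo <- if (arm == "p") 1L else cen + 1L
  hi <- if (arm == "p") cen else len
  n_seg <- n_transitions + 1L
  if (hi - lo + 1 < n_seg) stop("arm too short for requested transitions")
  if (n_transitions == 0L) return(segments)

  # alternate between two joint states differing in total_cn
  bounds <- lo + round(seq(0, hi - lo + 1, length.out = n_seg + 1))
  keep <- segments$chrom != chrom
  chr_seg <- segments[segments$chrom == chrom, ]
  chr_seg <- chr_seg[order(chr_seg$start), ]
  out <- list()
  for (j in seq_len(nrow(chr_seg))) {
    s <- chr_seg[j, ]
    if (s$end < lo || s$start > hi) { out[[length(out) + 1]] <- s; next }
    if (s$start < lo) { left <- s; left$end <- lo - 1L; out[[length(out) + 1]] <- left }
    if (s$end > hi) { right <- s; right$start <- hi + 1L; out[[length(out) + 1]] <- right }
  }
  for (j in seq_len(n_seg)) {
    sg <- chr_seg[1, ]
    sg$start <- bounds[j]
    sg$end <- bounds[j + 1] - 1L
    sg$total_cn <- if (j %% 2L == 1L) 2L else 1L
    sg$minor_cn <- if (j %% 2L == 1L) 1L else 0L
    sg$loh <- sg$minor_cn == 0L & sg$total_cn >= 1L
    out[[length(out) + 1]] <- sg
  }
  res <- rbind(segments[keep, ], do.call(rbind, out))
  res <- res[order(match(res$chrom, genome$chromosomes$chrom), res$start), ]
  rownames(res) <- NULL
  res
}
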