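#' Genome models
#'
#' A genome model is the coordinate scaffold the whole pipeline works on: a
#' set of chromosomes with lengths, a centromere position per chromosome
#' (splitting each chromosome into a p and a q arm), and a gene catalog of
#' 1-based inclusive intervals. All on-disk coordinates are 1-based
#' inclusive; internal interval algebra is 0-based half-open.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (positive integer bp).
#' @param centromeres data.frame with columns `chrom` and `position` (bp,
#'   strictly inside the chromosome).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive, within chromosome bounds, `start < end`).
#' @return An object of class `genome_model` (a list with elements
#'   `chromosomes`, `centromeres`, `genes`).
#' @examples
#' g <- genome_model(
#'   chromosomes = data.frame(chrom = "1", length = 1e6),
#'   centromeres = data.frame(chrom = "1", position = 4e5),
#'   genes = data.frame(gene = "GENE1", chrom = "1", start = 100, end = 5000))
#' genome_length(g)
#' @export
genome_model <- function(chromosomes, centromeres, genes) {
  stopifnot(is.data.frame(chromosomes), all(c("chrom", "length") %in% names(chromosomes)))
  stopifnot(is.data.frame(centromeres), all(c("chrom", "position") %in% names(centromeres)))
  stopifnot(is.data.frame(genes), all(c("gene", "chrom", "start", "end") %in% names(genes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  centromeres$chrom <- as.character(centromeres$chrom)
  genes$chrom <- as.character(genes$chrom)
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicate chromosome names")
  len <- stats::setNames(chromosomes$length, chromosomes$chrom)
  if (!all(centromeres$chrom %in% chromosomes$chrom))
    stop("centromere on unknown chromosome")
  if (any(centromeres$position <= 0 | centromeres$position >= len[centromeres$chrom]))
    stop("centromere must lie strictly inside its chromosome")
  if (!all(genes$chrom %in% chromosomes$chrom)) stop("gene on unknown chromosome")
  if (any(genes$start < 1 | genes$end > len[genes$chrom]))
    stop("gene outside chromosome bounds")
  if (any(genes$start >= genes$end)) stop("gene intervals must be non-degenerate")
  structure(list(chromosomes = chromosomes, centromeres = centromeres,
                 genes = genes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosomes, ",
      format(genome_length(x), big.mark = ","), " bp, ",
      nrow(x$genes), " catalogued genes\n", sep = "")
  invisible(x)
}

#' Total genome length in bp
#' @param genome a `genome_model`.
#' @export
genome_length <- function(genome) sum(as.numeric(genome$chromosomes$length))

#' Chromosome lengths as a named vector
#' @param genome a `genome_model`.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
}

# Arm (p/q) of positions on one chromosome, given the genome's centromere.
chrom_arm <- function(genome, chrom, pos) {
  cen <- genome$centromeres$position[match(chrom, genome$centromeres$chrom)]
  ifelse(pos <= cen, "p", "q")
}

# GRCh37 autosome lengths (bp) and approximate centromere midpoints, used to
# build the scaled default genome.
.grch37_lengths <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566)
.grch37_centromeres <- c(
  125.0, 93.3, 91.0, 50.4, 48.4, 61.0, 59.9, 45.6, 49.0, 40.2, 53.7, 35.8,
  17.9, 17.6, 19.0, 36.6, 24.0, 17.2, 26.5, 27.5, 13.2, 14.7) * 1e6

#' Scaled human-like default genome
#'
#' 22 autosomes with lengths and centromeres scaled from GRCh37 by
#' `1/scale_factor` (default 1/20, ~144 Mb total) so that whole-cohort
#' simulations run at desk scale; the downstream analysis is scale-free.
#' A small catalog of bladder-cancer-relevant genes (TP53, FGFR3, CDKN1A,
#' CDKN2A, MDM2, STAG2 placed on their native chromosomes at scaled
#' positions, plus anonymous filler genes) is included so that driver and
#' amplicon operations have anchors.
#'
#' @param scale_factor divide GRCh37 lengths by this (1 = full length).
#' @param n_filler_genes anonymous extra genes spread over the genome.
#' @return A `genome_model`.
#' @export
mini_genome <- function(scale_factor = 20, n_filler_genes = 40) {
  stopifnot(scale_factor >= 1)
  chrom <- as.character(1:22)
  len <- pmax(round(.grch37_lengths / scale_factor), 2e5)
  cen <- pmin(pmax(round(.grch37_centromeres / scale_factor), 1e4), len - 1e4)
  chromosomes <- data.frame(chrom = chrom, length = len)
  centromeres <- data.frame(chrom = chrom, position = cen)

  # Named driver genes at GRCh37 positions / scale_factor, width >= 20 kb so
  # they reliably intersect simulated segments.
  anchor <- function(gene, chr, start37, end37) {
    s <- max(1, round(start37 / scale_factor))
    e <- min(len[match(chr, chrom)], max(s + 20000, round(end37 / scale_factor)))
    data.frame(gene = gene, chrom = chr, start = s, end = e)
  }
  named <- rbind(
    anchor("TP53",   "17",  7565097,  7590856),
    anchor("FGFR3",  "4",   1795039,  1810599),
    anchor("CDKN1A", "6",  36644237, 36655116),
    anchor("CDKN2A", "9",  21967751, 21995300),
    anchor("MDM2",   "12", 69201971, 69239320),
    anchor("ARID1A", "1",  27022522, 27108601),
    anchor("STAG2",  "9", 99000000, 99100000),
    anchor("FAT1",   "4", 187508937, 187647876))
  # fixed catalog: filler placement is part of the model, drawn from a
  # private RNG stream so callers' seeds are unaffected
  placement <- .with_private_rng(20140429, {
    fill_chr <- sample(chrom, n_filler_genes, replace = TRUE)
    fill_start <- vapply(fill_chr, function(cc) {
      sample.int(len[match(cc, chrom)] - 30001L, 1L)
    }, integer(1))
    list(chr = fill_chr, start = fill_start)
  })
  fill_chr <- placement$chr
  fill_start <- placement$start
  filler <- data.frame(gene = sprintf("GENE%03d", seq_len(n_filler_genes)),
                       chrom = fill_chr, start = fill_start,
                       end = fill_start + 25000L)
  genes <- rbind(named, filler)
  rownames(genes) <- NULL
  genome_model(chromosomes, centromeres, genes)
}

# run expr under a private RNG stream, leaving the caller's untouched
.with_private_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
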