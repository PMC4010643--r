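#' The six strand-collapsed substitution classes
#'
#' Somatic base substitutions are conventionally collapsed over strand so
#' that the reference base is reported as a pyrimidine pair: a G>A change
#' is the same event as a C>T change on the opposite strand. The six
#' resulting classes, in the fixed order used throughout the package:
#' `C:G>T:A`, `C:G>A:T`, `C:G>G:C`, `T:A>C:G`, `T:A>A:T`, `T:A>G:C`.
#'
#' @return character vector of the six class labels.
#' @export
spectrum_classes <- function() {
  c("C:G>T:A", "C:G>A:T", "C:G>G:C", "T:A>C:G", "T:A>A:T", "T:A>G:C")
}

#' Classify a base substitution into its strand-collapsed class
#'
#' @param ref,alt single reference/alternate bases (vectors allowed; must
#'   be in `A`,`C`,`G`,`T` and differ element-wise).
#' @return character vector of class labels from [spectrum_classes()].
#' @examples
#' classify_substitution("C", "T")  # "C:G>T:A"
#' classify_substitution("G", "A")  # same class, opposite strand
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")             # purine reference: collapse
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  key <- paste0(r, ">", a)
  map <- c("C>T" = "C:G>T:A", "C>A" = "C:G>A:T", "C>G" = "C:G>G:C",
           "T>C" = "T:A>C:G", "T>A" = "T:A>A:T", "T>G" = "T:A>G:C")
  unname(map[key])
}

#' Compute the six-class substitution spectrum of a variant set
#'
#' Indels are skipped (their count is recorded on the profile); SNVs are
#' classified with [classify_substitution()] and tallied.
#'
#' @param variants data.frame with columns `ref`, `alt` and (optionally)
#'   `class`; rows with `class != "SNV"` or multi-base alleles are skipped.
#' @return An object of class `spectrum_profile`: list with `counts`
#'   (named integer, the six classes), `proportions`, `n_snv`,
#'   `n_skipped`, and `empty` (TRUE when no SNVs, in which case
#'   proportions are NA).
#' @export
compute_spectrum <- function(variants) {
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref != variants$alt
  if (!is.null(variants$class)) is_snv <- is_snv & variants$class == "SNV"
  snv <- variants[is_snv, , drop = FALSE]
  cls <- factor(if (nrow(snv)) classify_substitution(snv$ref, snv$alt)
                else character(0), levels = spectrum_classes())
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  structure(list(
    counts = counts,
    proportions = if (total > 0) counts / total else
      stats::setNames(rep(NA_real_, 6), spectrum_classes()),
    n_snv = total,
    n_skipped = nrow(variants) - nrow(snv),
    empty = total == 0), class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat("<spectrum_profile> ", x$n_snv, " SNVs (", x$n_skipped, " skipped)\n",
      sep = "")
  if (!x$empty)
    print(round(x$proportions, 3))
  invisible(x)
}

#' Compare a spectrum against reference class proportions
#'
#' Chi-square goodness-of-fit of the observed six-class counts against
#' expected counts `total * q`, plus the cosine similarity of the
#' proportion vectors. Expected cells below `min_expected` are merged into
#' their nearest (adjacent-index) neighbour before the chi-square sum, and
#' the degrees of freedom reduced accordingly.
#'
#' @param profile a `spectrum_profile` with total count > 0.
#' @param q reference proportions over the six classes (sum to 1).
#' @param min_expected merge threshold for small expected cells.
#' @return list(`chi_square`, `df`, `p_value`, `cosine`).
#' @export
compare_spectra <- function(profile, q, min_expected = 5) {
  stopifnot(inherits(profile, "spectrum_profile"))
  if (profile$empty) stop("cannot compare an empty spectrum")
  q <- as.numeric(q)
  if (length(q) != 6 || abs(sum(q) - 1) > 1e-9)
    stop("reference proportions must be 6 values summing to 1")
  obs <- as.numeric(profile$counts)
  expd <- profile$n_snv * q
  # merge any small expected cell into its nearest neighbour by index
  while (length(obs) > 1 && any(expd < min_expected)) {
    i <- which.min(expd)
    j <- if (i == 1) 2 else if (i == length(expd)) i - 1 else
      if (expd[i - 1] <= expd[i + 1]) i - 1 else i + 1
    obs[j] <- obs[j] + obs[i]; expd[j] <- expd[j] + expd[i]
    obs <- obs[-i]; expd <- expd[-i]
  }
  term <- ifelse(expd == 0, ifelse(obs == 0, 0, Inf),
                 (obs - expd)^2 / expd)
  chi <- sum(term)
  df <- length(obs) - 1
  p <- as.numeric(profile$proportions)
  cosine <- if (sqrt(sum(p^2)) * sqrt(sum(q^2)) == 0) NA_real_ else
    sum(p * q) / (sqrt(sum(p^2)) * sqrt(sum(q^2)))
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE),
       cosine = cosine)
}

#' Spectrum of the variants overlapping a region set
#'
#' Restricts a variant table to those falling inside a collection of
#' genomic intervals (for example an exome definition) and computes the
#' spectrum of the subset, enabling exome-versus-genome comparisons.
#'
#' @param variants variant data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive); zero rows give an empty profile.
#' @return a `spectrum_profile`.
#' @export
subset_spectrum <- function(variants, regions) {
  if (nrow(regions) == 0) return(compute_spectrum(variants[0, , drop = FALSE]))
  keep <- overlaps_any(variants$chrom, variants$pos, variants$pos, regions)
  compute_spectrum(variants[keep, , drop = FALSE])
}

# TRUE for each query interval that overlaps >= 1 bp of the region set
overlaps_any <- function(chrom, start, end, regions) {
  out <- logical(length(chrom))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    reg <- regions[regions$chrom == cc, , drop = FALSE]
    if (nrow(reg) == 0) next
    q <- IRanges::IRanges(start = start[sel], end = end[sel])
    s <- IRanges::IRanges(start = reg$start, end = reg$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}
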