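#' Attach plausible annotations to synthetic variants
#'
#' Gives generator output the annotation columns the driver cascade
#' consumes: `gene` by overlap with the genome's catalog, a consequence
#' class (indels in genes become frameshift/splice-site; SNVs in genes
#' missense/synonymous/stop-gain/splice-site; everything else
#' intergenic), SIFT and PolyPhen2 scores for missense changes (uniform
#' on [0,1]), and a sparse `pop_af` column so the population filter has
#' something to act on.
#'
#' @param variants variant data.frame.
#' @param genome a `genome_model`.
#' @param seed RNG seed.
#' @param af_rate fraction of variants given a population frequency.
#' @return the annotated data.frame.
#' @export
simulate_annotations <- function(variants, genome, seed, af_rate = 0.02) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  n <- nrow(variants)
  genes <- genome$genes
  gene <- rep(NA_character_, n)
  for (cc in unique(variants$chrom)) {
    sel <- which(variants$chrom == cc)
    gg <- genes[genes$chrom == cc, , drop = FALSE]
    if (!nrow(gg)) next
    q <- IRanges::IRanges(variants$pos[sel], variants$pos[sel])
    s <- IRanges::IRanges(gg$start, gg$end)
    hit <- IRanges::findOverlaps(q, s, select = "first")
    gene[sel] <- gg$gene[hit]
  }
  in_gene <- !is.na(gene)
  is_snv <- variants$class == "SNV"
  cons <- rep("intergenic", n)
  cons[in_gene & is_snv] <- sample(
    c("missense", "synonymous", "stop-gain", "stop-loss", "splice-site",
      "UTR"),
    sum(in_gene & is_snv), replace = TRUE,
    prob = c(0.45, 0.25, 0.05, 0.01, 0.04, 0.20))
  cons[in_gene & !is_snv] <- sample(
    c("frameshift", "splice-site", "UTR"),
    sum(in_gene & !is_snv), replace = TRUE, prob = c(0.6, 0.1, 0.3))
  sift <- rep(NA_real_, n); pp2 <- rep(NA_real_, n)
  mis <- cons == "missense"
  sift[mis] <- round(stats::runif(sum(mis)), 3)
  pp2[mis] <- round(stats::runif(sum(mis)), 3)
  pop_af <- rep(NA_real_, n)
  known <- stats::runif(n) < af_rate
  pop_af[known] <- round(stats::runif(sum(known), 0, 0.2), 3)
  variants$gene <- gene
  variants$consequence <- cons
  variants$sift <- sift
  variants$polyphen2 <- pp2
  variants$pop_af <- pop_af
  variants
}

#' Consequence class inferred from an HGVS-style protein change
#'
#' Used when ingesting driver tables that report mutations as
#' transcript:DNA:protein strings: `fs` means frameshift, a trailing `X`
#' (or `delinsX`) a stop-gain, `del` without frameshift an in-frame
#' deletion (treated as missense-like), anything else missense.
#'
#' @param detail character vector of HGVS-like strings.
#' @return character vector of consequence classes.
#' @export
consequence_from_detail <- function(detail) {
  out <- rep("missense", length(detail))
  out[grepl("fs$|fs\\b", detail)] <- "frameshift"
  out[grepl("X$|delinsX", detail)] <- "stop-gain"
  out
}

#' Validate a pipeline run configuration
#'
#' Fails fast (before any compute) on invalid thresholds or missing
#' inputs. See [run_pipeline()] for the recognised fields.
#'
#' @param config list or path to a YAML file.
#' @return the normalized config list, invisibly on success.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    mode = "synthetic", out_dir = NULL, seed = NULL,
    stages = list(spectrum = TRUE, drivers = TRUE, hotspots = TRUE,
                  cna = TRUE, clonality = TRUE, associations = TRUE),
    thresholds = list(min_depth = 10, max_af = 0.05, window_size = 1e6,
                      alpha = 0.05, min_transitions = 10,
                      recurrence_min_samples = 2, amplicon_cn = 3),
    genome_scale = 20,
    cohort = list(),
    clonality_method = "bins")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$thresholds))
    if (is.null(config$thresholds[[nm]]))
      config$thresholds[[nm]] <- defaults$thresholds[[nm]]
  for (nm in names(defaults$stages))
    if (is.null(config$stages[[nm]])) config$stages[[nm]] <- TRUE
  th <- config$thresholds
  if (th$window_size <= 0) stop("window_size must be positive")
  if (th$min_depth < 0) stop("min_depth must be >= 0")
  if (th$alpha <= 0 || th$alpha > 1) stop("alpha must be in (0, 1]")
  if (th$min_transitions < 0) stop("min_transitions must be >= 0")
  if (!config$mode %in% c("synthetic", "fixture"))
    stop("mode must be 'synthetic' or 'fixture'")
  if (config$mode == "synthetic" && is.null(config$seed))
    stop("a seed is mandatory in synthetic mode")
  invisible(config)
}

#' Run the somatic-genome analysis pipeline end to end
#'
#' In `synthetic` mode, generates a cohort with [generate_cohort()] and
#' runs every enabled stage: record-level filters, per-sample and pooled
#' mutation spectra, the driver cascade, 1-Mb hotspot scan, copy-number
#' burden / chromothripsis / recurrent regions, clonal clustering, and
#' the burden-association screen on the resulting cohort summary. In
#' `fixture` mode, loads the packaged published tables and runs only the
#' association and driver-matrix stages. Per-stage TSVs and a run log
#' (package version, seed, every threshold) are written when `out_dir`
#' is set; rerunning the same config reproduces the deterministic stages
#' byte-identically.
#'
#' @param config list or YAML path; fields: `mode`, `seed`, `out_dir`,
#'   `stages` (logical toggles), `thresholds`, `genome_scale`, `cohort`
#'   (overrides for [cohort_config()]), `clonality_method`
#'   ("bins"/"dp").
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  th <- config$thresholds
  out <- list(config = config)
  emit <- function(name, df) {
    out[[name]] <<- df
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(config$out_dir,
                                       paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (config$mode == "fixture") {
    summary <- load_cohort_summary()
    drivers <- load_driver_table()
    if (isTRUE(config$stages$drivers)) {
      dv <- data.frame(sample = drivers$tumour, gene = drivers$gene,
                       consequence = consequence_from_detail(drivers$detail),
                       loh = drivers$loh %in% 1)
      m <- build_gene_sample_matrix(dv)
      emit("driver_matrix", data.frame(gene = rownames(m$counts),
                                       n_samples = rowSums(m$counts > 0),
                                       n_mutations = rowSums(m$counts),
                                       n_loh = rowSums(m$loh)))
      out$gene_sample_matrix <- m
    }
    if (isTRUE(config$stages$associations)) {
      emit("associations", association_screen(
        summary, burden_vars = c("gsm", "cnv_pct", "clonality"),
        factors = c("stage", "grade", "age", "sex", "smoker"),
        pooling = list(stage = list("pTa", c("pT1", "pT2")),
                       grade = list(c("G1", "G2", "G1-2"), "G3"),
                       smoker = list("Never",
                                     c("Ex", "Current", "Passive")))))
    }
    .write_run_log(config, out)
    return(invisible(out))
  }

  genome <- mini_genome(scale_factor = config$genome_scale)
  cc_args <- config$cohort
  cc_args$seed <- config$seed
  cohort <- generate_cohort(do.call(cohort_config, cc_args), genome)
  variants <- depth_filter(cohort$variants, th$min_depth)
  out$cohort <- cohort

  if (isTRUE(config$stages$spectrum)) {
    pooled <- compute_spectrum(variants)
    per_sample <- do.call(rbind, lapply(split(variants, variants$sample),
      function(v) {
        p <- compute_spectrum(v)
        data.frame(sample = v$sample[1], class = spectrum_classes(),
                   count = as.integer(p$counts),
                   proportion = as.numeric(p$proportions))
      }))
    rownames(per_sample) <- NULL
    emit("spectrum", per_sample)
    out$pooled_spectrum <- pooled
  }

  if (isTRUE(config$stages$drivers)) {
    ann <- simulate_annotations(variants, genome, seed = config$seed + 1)
    ann <- population_filter(ann, th$max_af)
    m <- driver_cascade(ann, min_samples = th$recurrence_min_samples)
    emit("driver_matrix", data.frame(gene = rownames(m$counts),
                                     n_samples = rowSums(m$counts > 0),
                                     n_mutations = rowSums(m$counts)))
    out$gene_sample_matrix <- m
  }

  if (isTRUE(config$stages$hotspots)) {
    hs <- do.call(rbind, lapply(split(variants, variants$sample),
      function(v) {
        seg <- cohort$segments[cohort$segments$sample == v$sample[1], ]
        rec <- call_hotspots(window_counts(v, genome, th$window_size),
                             alpha = th$alpha)
        rec <- annotate_explanations(rec, seg, genome)
        cbind(sample = v$sample[1], rec)
      }))
    rownames(hs) <- NULL
    emit("hotspots", hs[hs$hotspot, , drop = FALSE])
    out$window_scan <- hs
  }

  summary <- cohort$samples
  summary$gsm <- as.integer(table(factor(
    variants$sample[variants$class == "SNV"],
    levels = summary$sample)))
  if (isTRUE(config$stages$cna)) {
    summary$cnv_pct <- vapply(summary$sample, function(sm)
      fraction_genome_altered(
        cohort$segments[cohort$segments$sample == sm, ], genome),
      numeric(1))
    summary$n_cnvs <- vapply(summary$sample, function(sm) {
      seg <- cohort$segments[cohort$segments$sample == sm, ]
      sum(seg$total_cn != 2 | seg$loh)
    }, integer(1))
    emit("chromothripsis",
         chromothripsis_scan(cohort$segments, genome,
                             th$min_transitions))
    emit("recurrent_gains",
         recurrent_regions(cohort$segments,
                           min_samples = max(2, ceiling(nrow(summary) / 3)),
                           event = "gain"))
    emit("homozygous_deletions",
         homozygous_deletions(cohort$segments, genome))
  }

  if (isTRUE(config$stages$clonality)) {
    summary$clonality <- vapply(summary$sample, function(sm) {
      v <- variants[variants$sample == sm & variants$class == "SNV", ]
      v <- v[v$total_cn > 0, ]
      if (nrow(v) > 50) v <- v[sort(sample.int(nrow(v), 50)), ]
      fit <- if (config$clonality_method == "dp")
        cluster_prevalences(estimate_prevalence(v), seed = config$seed + 2)
      else cluster_prevalences(estimate_prevalence(v), method = "bins")
      fit$n_clusters
    }, integer(1))
  }
  emit("cohort_summary", summary)

  if (isTRUE(config$stages$associations)) {
    bv <- intersect(c("gsm", "cnv_pct", "clonality"), names(summary))
    emit("associations", association_screen(
      summary, burden_vars = bv, factors = c("stage", "grade"),
      pooling = list(stage = list("pTa", c("pT1", "pT2")),
                     grade = list("G1-2", "G3"))))
  }

  .write_run_log(config, out)
  invisible(out)
}

.write_run_log <- function(config, out) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  lines <- c(
    paste0("uroscape ", as.character(utils::packageVersion("uroscape"))),
    paste0("mode: ", config$mode),
    paste0("seed: ", config$seed %||% "none"),
    paste0("clonality_method: ", config$clonality_method),
    vapply(names(config$thresholds), function(nm)
      paste0("threshold ", nm, ": ", config$thresholds[[nm]]),
      character(1)),
    vapply(names(config$stages), function(nm)
      paste0("stage ", nm, ": ", config$stages[[nm]]), character(1)))
  writeLines(lines, file.path(config$out_dir, "run_log.txt"))
  invisible(NULL)
}
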