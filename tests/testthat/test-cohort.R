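test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(prevalences = list(pTa = 1.5), seed = 1),
               "prevalences")
  expect_error(cohort_config(purity = 0, seed = 1), "purity")
  expect_error(cohort_config(spectrum = rep(0.2, 6), seed = 1), "sum")
  expect_error(cohort_config(), "seed")
  expect_error(generate_cohort(
    cohort_config(amplicon = list(gene = "NOSUCH", levels = 8), seed = 1)),
    "anchor gene")
})

test_that("same seed gives identical cohorts", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a, b)
  expect_false(identical(small_cohort(seed = 8)$variants, a$variants))
})

test_that("pure monoclonal diploid sample has expected VAF 1/2", {
  co <- generate_cohort(cohort_config(
    n_samples = c(pTa = 1L), mean_snv = c(pTa = 3000),
    prevalences = list(pTa = 1), purity = c(pTa = 1),
    seg_rates = c(gain = 0, loss = 0, cnloh = 0, homdel = 0),
    depth_mean = 500, seed = 5), mini_genome())
  v <- co$variants
  expect_true(all(v$total_cn == 2))
  # empirical VAF tightly around 0.5 at depth 500
  expect_lt(abs(mean(v$alt_reads / v$depth) - 0.5), 0.005)
})

test_that("segments tile each chromosome exactly once (interval sweep)", {
  co <- small_cohort(seed = 11)
  g <- mini_genome()
  for (sm in unique(co$segments$sample)) {
    seg <- co$segments[co$segments$sample == sm, ]
    for (i in seq_len(nrow(g$chromosomes))) {
      cc <- g$chromosomes$chrom[i]
      s <- seg[seg$chrom == cc, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 1)
      expect_equal(s$end[nrow(s)], g$chromosomes$length[i])
      if (nrow(s) > 1)
        expect_true(all(s$start[-1] == s$end[-nrow(s)] + 1))
    }
  }
})

test_that("empirical group mean burden stays within 3 Poisson SD of target", {
  co <- generate_cohort(cohort_config(
    n_samples = c(pTa = 4L, invasive = 10L),
    mean_snv = c(pTa = 35000, invasive = 115000),
    prevalences = list(pTa = 1, invasive = c(1, 0.4)),
    purity = c(pTa = 0.8, invasive = 0.8), seed = 21), mini_genome())
  snv <- co$variants[co$variants$class == "SNV", ]
  counts <- table(snv$sample)
  for (grp in c("pTa", "invasive")) {
    sm <- co$samples$sample[co$samples$stage == grp]
    mu <- c(pTa = 35000, invasive = 115000)[[grp]]
    se <- sqrt(mu / length(sm))     # Poisson sampling oracle
    expect_lt(abs(mean(counts[sm]) - mu), 3 * se)
  }
})

test_that("simulated spectrum recovers configured class probabilities", {
  probs <- c(0.4, 0.1, 0.1, 0.25, 0.1, 0.05)
  co <- generate_cohort(cohort_config(
    n_samples = c(pTa = 1L), mean_snv = c(pTa = 10000), indel_ratio = 0,
    prevalences = list(pTa = 1), spectrum = probs, seed = 9),
    mini_genome())
  sp <- compute_spectrum(co$variants)
  n <- sp$n_snv
  se <- sqrt(probs * (1 - probs) / n)  # multinomial oracle
  expect_true(all(abs(as.numeric(sp$proportions) - probs) < 3 * se))
})

test_that("stage-monotone configured burden gives monotone group medians", {
  ok <- 0L
  for (seed in 1:20) {
    co <- generate_cohort(cohort_config(
      n_samples = c(pTa = 4L, pT1 = 4L, pT2 = 4L),
      mean_snv = c(pTa = 1000, pT1 = 2000, pT2 = 4000),
      prevalences = list(pTa = 1, pT1 = 1, pT2 = 1),
      het_density = 0, seed = seed), mini_genome())
    snv <- co$variants[co$variants$class == "SNV", ]
    n <- table(factor(snv$sample, levels = co$samples$sample))
    med <- tapply(as.integer(n), co$samples$stage, median)
    if (med[["pTa"]] < med[["pT1"]] && med[["pT1"]] < med[["pT2"]])
      ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("indel counts are correlated with SNV counts", {
  co <- generate_cohort(cohort_config(
    n_samples = c(pTa = 4L, pT1 = 4L),
    mean_snv = c(pTa = 500, pT1 = 5000),
    prevalences = list(pTa = 1, pT1 = 1), seed = 13), mini_genome())
  tab <- table(co$variants$sample, co$variants$class)
  expect_gt(cor(tab[, "SNV"], tab[, "indel"]), 0.9)
})

test_that("amplicon injection produces the requested copy levels", {
  g <- mini_genome()
  seg <- diploid_segments(g, "S1")
  amp <- inject_amplicon(seg, g, "MDM2", levels = c(8L, 3L))
  mdm2 <- g$genes[g$genes$gene == "MDM2", ]
  hit <- amp[amp$chrom == mdm2$chrom & amp$start <= mdm2$end &
               amp$end >= mdm2$start, ]
  expect_true(8L %in% hit$total_cn)
  expect_setequal(setdiff(amp$total_cn, 2L), c(8L, 3L))
  # still a tiling
  expect_silent(uroscape:::.check_tiling(amp, g))
})
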