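test_that("fraction of genome altered handles the canonical cases", {
  g <- tiny_genome()   # 16 Mb total
  seg <- diploid_segments(g)
  expect_equal(fraction_genome_altered(seg, g), 0)
  loss <- transform(seg, total_cn = 1L, minor_cn = 0L, loh = TRUE)
  expect_equal(fraction_genome_altered(loss, g), 100)
  # half of the genome gained: chromosome 1 first 8 Mb at CN 3
  seg2 <- rbind(
    data.frame(sample = "S", chrom = "1", start = 1, end = 8e6,
               total_cn = 3L, minor_cn = 1L, loh = FALSE),
    data.frame(sample = "S", chrom = "1", start = 8e6 + 1, end = 10e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE),
    data.frame(sample = "S", chrom = "2", start = 1, end = 6e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE))
  expect_equal(fraction_genome_altered(seg2, g), 50)
  # copy-neutral LOH counts as altered
  cnloh <- transform(seg, minor_cn = 0L, loh = TRUE)
  expect_equal(fraction_genome_altered(cnloh, g), 100)
  # gaps are an error naming the gap
  gap <- seg2[-2, ]
  expect_error(fraction_genome_altered(gap, g), "1:8000001-10000000")
})

test_that("altered fraction is invariant to state-preserving splits", {
  g <- tiny_genome()
  seg <- rbind(
    data.frame(sample = "S", chrom = "1", start = 1, end = 5e6,
               total_cn = 3L, minor_cn = 1L, loh = FALSE),
    data.frame(sample = "S", chrom = "1", start = 5e6 + 1, end = 10e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE),
    data.frame(sample = "S", chrom = "2", start = 1, end = 6e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE))
  split1 <- rbind(
    data.frame(sample = "S", chrom = "1", start = c(1, 2e6 + 1),
               end = c(2e6, 5e6), total_cn = 3L, minor_cn = 1L,
               loh = FALSE),
    seg[-1, ])
  expect_equal(fraction_genome_altered(split1, g),
               fraction_genome_altered(seg, g))
})

test_that("chromothripsis transition counting is runs minus one", {
  g <- tiny_genome()
  # arm q of chromosome 1 spans 4e6+1 .. 10e6
  mk_arm <- function(n_seg) {
    bounds <- round(seq(4e6 + 1, 10e6 + 1, length.out = n_seg + 1))
    data.frame(sample = "S", chrom = "1",
               start = bounds[-length(bounds)],
               end = bounds[-1] - 1,
               total_cn = rep(c(2L, 1L), length.out = n_seg),
               minor_cn = rep(c(1L, 0L), length.out = n_seg),
               loh = rep(c(FALSE, TRUE), length.out = n_seg))
  }
  base <- rbind(
    data.frame(sample = "S", chrom = "1", start = 1, end = 4e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE),
    data.frame(sample = "S", chrom = "2", start = 1, end = 6e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE))
  for (n_seg in c(10, 11, 12)) {
    seg <- rbind(base, mk_arm(n_seg))
    sc <- chromothripsis_scan(seg, g)
    row <- sc[sc$chrom == "1" & sc$arm == "q", ]
    expect_equal(row$n_transitions, n_seg - 1)
    expect_equal(row$flagged, n_seg - 1 >= 10)
  }
})

test_that("LOH-only state changes count as transitions", {
  g <- tiny_genome()
  # 11 segments: 5 boundaries change CN, 5 change LOH only -> 10 total
  states <- data.frame(
    total_cn = c(2L, 3L, 3L, 2L, 2L, 3L, 3L, 2L, 2L, 3L, 3L),
    minor_cn = c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  states$loh <- states$minor_cn == 0L
  bounds <- round(seq(4e6 + 1, 10e6 + 1, length.out = 12))
  arm <- data.frame(sample = "S", chrom = "1",
                    start = bounds[-12], end = bounds[-1] - 1,
                    total_cn = states$total_cn, minor_cn = states$minor_cn,
                    loh = states$loh)
  seg <- rbind(
    data.frame(sample = "S", chrom = "1", start = 1, end = 4e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE),
    data.frame(sample = "S", chrom = "2", start = 1, end = 6e6,
               total_cn = 2L, minor_cn = 1L, loh = FALSE), arm)
  sc <- chromothripsis_scan(seg, g)
  row <- sc[sc$chrom == "1" & sc$arm == "q", ]
  expect_equal(row$n_transitions, 10)
  expect_true(row$flagged)
})

test_that("injected chromothripsis is detected at the defined threshold", {
  g <- mini_genome()
  seg <- diploid_segments(g, "S1")
  for (n in c(0, 9, 10, 11)) {
    s2 <- inject_chromothripsis(seg, g, "5", "q", n)
    sc <- chromothripsis_scan(s2, g)
    row <- sc[sc$chrom == "5" & sc$arm == "q", ]
    expect_equal(row$n_transitions, n)
    expect_equal(row$flagged, n >= 10)
  }
  expect_error(inject_chromothripsis(seg, g, "5", "q", 10e6), "too short")
})

test_that("recurrent regions match the per-base counting oracle", {
  g <- genome_model(
    chromosomes = data.frame(chrom = "1", length = 1000L),
    centromeres = data.frame(chrom = "1", position = 500L),
    genes = data.frame(gene = "G", chrom = "1", start = 1L, end = 10L))
  set.seed(14)
  seg <- do.call(rbind, lapply(1:8, function(s) {
    cuts <- sort(sample(2:999, 4))
    starts <- c(1L, cuts); ends <- c(cuts - 1L, 1000L)
    data.frame(sample = paste0("S", s), chrom = "1", start = starts,
               end = ends,
               total_cn = sample(c(1L, 2L, 3L), 5, TRUE),
               minor_cn = 1L, loh = FALSE)
  }))
  for (min_n in c(2, 4, 6)) {
    rr <- recurrent_regions(seg, min_samples = min_n, event = "gain")
    oracle <- per_base_recurrence(seg, 1000L, "gain")
    covered <- logical(1000)
    if (nrow(rr))
      for (i in seq_len(nrow(rr))) {
        covered[rr$start[i]:rr$end[i]] <- TRUE
        expect_true(all(oracle[rr$start[i]:rr$end[i]] == rr$n_samples[i]))
      }
    expect_identical(covered, oracle >= min_n)
  }
  # single-sample event never reaches min_samples = 6
  one <- seg[seg$sample == "S1" & seg$total_cn > 2, ]
  expect_equal(nrow(recurrent_regions(one, min_samples = 6, "gain")), 0)
})

test_that("shared arm gains are reported as one recurrent region", {
  seg <- do.call(rbind, lapply(1:6, function(s)
    data.frame(sample = paste0("S", s), chrom = "1",
               start = 4e6 + 1, end = 10e6, total_cn = 3L, minor_cn = 1L,
               loh = FALSE)))
  rr <- recurrent_regions(seg, min_samples = 6, event = "gain")
  expect_equal(nrow(rr), 1)
  expect_equal(rr$start, 4e6 + 1)
  expect_equal(rr$end, 10e6)
  expect_equal(rr$n_samples, 6L)
})

test_that("homozygous deletions require >= 1 bp gene overlap", {
  g <- tiny_genome()  # GENEA at 1:100001-150000
  mk <- function(start, end, cn)
    data.frame(sample = "S1", chrom = "1", start = start, end = end,
               total_cn = cn, minor_cn = 0L, loh = cn >= 1)
  expect_equal(homozygous_deletions(mk(90000, 100001, 0L), g)$gene, "GENEA")
  expect_equal(nrow(homozygous_deletions(mk(90000, 100000, 0L), g)), 0)
  expect_equal(nrow(homozygous_deletions(mk(90000, 200000, 1L), g)), 0)
})

test_that("expected heterozygote BAF follows the allele-ratio formula", {
  expect_equal(expected_het_baf(2, 1, 1), 0.5)
  expect_equal(expected_het_baf(3, 2, 1), 2 / 3)
  expect_equal(expected_het_baf(8, 7, 1), 0.875)
  # purity dilutes toward 0.5
  expect_equal(expected_het_baf(8, 7, 0.5), (0.5 * 7 + 0.5) / (0.5 * 8 + 1))
  expect_error(expected_het_baf(2, 3, 1))
})

test_that("amplicon profiling grows the region and measures asymmetry", {
  g <- mini_genome()
  seg <- inject_amplicon(diploid_segments(g, "S1"), g, "MDM2",
                         levels = c(8L, 3L))
  mdm2 <- g$genes[g$genes$gene == "MDM2", ]
  # hets inside the CN=8 stretch at the theoretical major BAF
  amp8 <- seg[seg$total_cn == 8L, ]
  hets <- data.frame(sample = "S1", chrom = "12",
                     pos = round(seq(amp8$start, amp8$end, length.out = 5)),
                     tumour_baf = 0.875, constitutional_baf = 0.5)
  v0 <- data.frame(sample = "S1", chrom = "12", pos = amp8$start + 10,
                   ref = "C", alt = "T", class = "SNV", depth = 100L,
                   alt_reads = 40L)
  prof <- amplicon_profile(v0, hets, seg, g, "MDM2")
  expect_false(prof$empty)
  expect_equal(prof$asymmetry, 0.375)
  expect_true(all(c(8L, 3L) %in% prof$cn_track$total_cn))
  expect_gte(mdm2$start, prof$region$start)
  # region is the contiguous amplified run, not the whole chromosome
  expect_lt(prof$region$end - prof$region$start, 1e7)

  # balanced diploid region: asymmetry ~ 0 (profiled at threshold 2)
  dip <- diploid_segments(g, "S1")
  hets2 <- transform(hets, tumour_baf = 0.5)
  prof2 <- amplicon_profile(v0, hets2, dip, g, "MDM2", cn_threshold = 2)
  expect_equal(prof2$asymmetry, 0)

  # no amplified segment at default threshold: empty profile with reason
  prof3 <- amplicon_profile(v0, hets, dip, g, "MDM2")
  expect_true(prof3$empty)
  expect_match(prof3$reason, "no segment")
})

test_that("amplicon mutation excess matches the density-ratio oracle", {
  g <- flat_genome(100)  # 100 Mb
  region <- list(chrom = "1", start = 50e6 + 1, end = 51e6)
  set.seed(3)
  out_pos <- sample(c(1:50000000, 51000001:100000000), 990)
  in_pos <- sample(region$start:region$end, 100)
  v <- data.frame(chrom = "1", pos = c(out_pos, in_pos),
                  class = "indel")
  seg <- data.frame(sample = "S", chrom = "1",
                    start = c(1, region$start, region$end + 1),
                    end = c(region$start - 1, region$end, 100e6),
                    total_cn = c(2L, 4L, 2L), minor_cn = 1L, loh = FALSE)
  ex <- amplicon_mutation_excess(v, region, seg, g)
  # oracle: (100 / 1e6) / (990 / 99e6) = 10
  expect_equal(ex$indel_ratio, 10)
  expect_equal(ex$mean_cn, 4)
  expect_equal(ex$indel_ratio_cn_adjusted, 5)  # still elevated after CN
  expect_error(amplicon_mutation_excess(
    v, list(chrom = "1", start = 10, end = 9), seg, g), "zero-length")
})

test_that("background-density region has excess ratio near one", {
  g <- flat_genome(100)
  set.seed(4)
  v <- data.frame(chrom = "1", pos = sample.int(100e6, 20000),
                  class = "SNV")
  region <- list(chrom = "1", start = 40e6 + 1, end = 60e6)
  seg <- diploid_segments(g, "S")
  ex <- amplicon_mutation_excess(v, region, seg, g)
  expect_lt(abs(ex$snv_ratio - 1), 0.15)
})
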