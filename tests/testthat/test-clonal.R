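test_that("variant selection adds a deterministic random draw", {
  co <- small_cohort(seed = 41, n_samples = c(pTa = 1L),
                     mean_snv = c(pTa = 2000), prevalences = list(pTa = 1))
  snv <- co$variants[co$variants$class == "SNV", ]
  cand <- snv[1:5, ]
  sel <- select_variants(cand, snv[-(1:5), ], n_random = 50, seed = 2)
  expect_equal(nrow(sel), 55)
  expect_equal(sum(sel$selection == "candidate"), 5)
  sel2 <- select_variants(cand, snv[-(1:5), ], n_random = 50, seed = 2)
  expect_identical(sel, sel2)
  expect_equal(nrow(select_variants(cand, snv[-(1:5), ], n_random = 0,
                                    seed = 2)), 5)
})

test_that("prevalence estimator applies the purity/CN adjustment", {
  mk <- function(alt, depth, cn, t, m = 1)
    data.frame(alt_reads = alt, depth = depth, total_cn = cn,
               purity = t, multiplicity = m)
  expect_equal(estimate_prevalence(mk(50, 100, 2, 1))$prevalence, 1.0)
  expect_equal(estimate_prevalence(mk(40, 100, 2, 0.8))$prevalence, 1.0)
  expect_equal(estimate_prevalence(mk(25, 100, 2, 1))$prevalence, 0.5)
  # clamping is flagged
  high <- estimate_prevalence(mk(90, 100, 2, 1))
  expect_equal(high$prevalence, 1.0)
  expect_true(high$clamped)
  # CN-zero loci are excluded with a message
  expect_message(out <- estimate_prevalence(rbind(mk(10, 100, 0, 1),
                                                  mk(50, 100, 2, 1))),
                 "excluded")
  expect_equal(nrow(out), 1)
})

test_that("prevalence estimator inverts the generator at high depth", {
  set.seed(6)
  f <- runif(300, 0.1, 0.9)
  cn <- sample(1:2, 300, TRUE)
  vaf <- f / cn                       # purity 1
  obs <- data.frame(alt_reads = rbinom(300, 1000, vaf), depth = 1000,
                    total_cn = cn, purity = 1)
  est <- estimate_prevalence(obs)
  expect_lt(median(abs(est$prevalence - f)), 0.02)
})

test_that("tight identical prevalences collapse to one cluster", {
  set.seed(2)
  obs <- data.frame(alt_reads = rbinom(40, 1000, 0.25), depth = 1000,
                    total_cn = 2, purity = 1)
  fit <- cluster_prevalences(estimate_prevalence(obs), seed = 4,
                             n_iterations = 600, burn_in = 200)
  expect_equal(fit$n_clusters, 1)
  expect_lt(abs(fit$clusters$prevalence - 0.5), 0.05)
})

test_that("deterministic bin fallback merges adjacent occupied bins", {
  obs <- data.frame(prevalence = c(0.18, 0.22, 0.95, 1.0))
  fit <- cluster_prevalences(obs, method = "bins")
  expect_equal(fit$n_clusters, 2)
  expect_equal(fit$assignments, c(1L, 1L, 2L, 2L))
  # far-apart bins stay separate
  obs2 <- data.frame(prevalence = c(0.1, 0.5, 0.95))
  expect_equal(cluster_prevalences(obs2, method = "bins")$n_clusters, 3)
})

test_that("cluster count is stable across seeds for separated clones", {
  set.seed(9)
  mkgrp <- function(f, n) data.frame(
    alt_reads = rbinom(n, 150, f * 0.5), depth = 150, total_cn = 2,
    purity = 1)
  obs <- estimate_prevalence(rbind(mkgrp(1.0, 30), mkgrp(0.45, 30)))
  ks <- vapply(1:5, function(s)
    cluster_prevalences(obs, seed = s, n_iterations = 800,
                        burn_in = 300)$n_clusters, integer(1))
  expect_true(all(ks == 2))
})

test_that("reported partition is invariant to input label permutation", {
  set.seed(12)
  obs <- estimate_prevalence(data.frame(
    alt_reads = rbinom(60, 200, rep(c(0.5, 0.1), each = 30)),
    depth = 200, total_cn = 2, purity = 1))
  fit1 <- cluster_prevalences(obs, seed = 3, n_iterations = 600,
                              burn_in = 200)
  perm <- sample.int(60)
  fit2 <- cluster_prevalences(obs[perm, ], seed = 3, n_iterations = 600,
                              burn_in = 200)
  # same partition up to relabeling
  expect_equal(mclust::adjustedRandIndex(fit1$assignments[perm],
                                         fit2$assignments), 1)
})

test_that("empty candidate plumbing still yields a valid clustering", {
  co <- small_cohort(seed = 43, n_samples = c(pTa = 1L),
                     mean_snv = c(pTa = 500), prevalences = list(pTa = 1))
  snv <- co$variants[co$variants$class == "SNV" & co$variants$total_cn > 0, ]
  sel <- select_variants(snv[0, ], snv, n_random = 50, seed = 5)
  fit <- cluster_prevalences(estimate_prevalence(sel), method = "bins")
  expect_s3_class(fit, "clone_fit")
  expect_gte(fit$n_clusters, 1)
  expect_equal(length(fit$assignments), nrow(fit$obs))
})

test_that("DNA-index sensitivity reruns agree for stable candidates", {
  set.seed(15)
  obs <- data.frame(
    alt_reads = rbinom(60, 200, rep(c(0.5, 0.1), each = 30)),
    depth = 200, total_cn = 2, purity = 1)
  sens <- sensitivity_over_dna_index(obs, c(1, 1, 1), method = "bins")
  expect_equal(sens$n_clusters[1], sens$n_clusters[2])
  expect_true(sens$qualitative_agreement)
  # degenerate purity: clamp-dominated, flagged unreliable
  obs2 <- transform(obs, purity = 0.01)
  sens2 <- sensitivity_over_dna_index(obs2, c(1), method = "bins")
  expect_true(sens2$unreliable[1])
})

test_that("clone_fit methods print, summarize and plot", {
  obs <- data.frame(prevalence = c(0.2, 0.21, 0.9, 0.95))
  fit <- cluster_prevalences(obs, method = "bins")
  expect_output(print(fit), "clonal cluster")
  expect_output(summary(fit), "Clonal clustering")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
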