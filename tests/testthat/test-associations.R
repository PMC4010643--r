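test_that("spearman handles monotone and tied inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x^3 + 1)$rho, 1)
  expect_equal(spearman_rho(x, -exp(x))$rho, -1)
  # invariance under strictly monotone transforms
  y <- c(2, 7, 1, 8, 2.8, 5)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(log(x), y^3)$rho)
  # agreement with the standard implementation (tie-aware)
  set.seed(1)
  a <- sample(1:8, 20, TRUE); b <- sample(1:8, 20, TRUE)
  ours <- spearman_rho(a, b)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("rank-sum test matches the tie-corrected normal approximation", {
  set.seed(2)
  for (i in 1:10) {
    a <- sample(1:10, 6, TRUE); b <- sample(1:10, 9, TRUE)
    ours <- wilcoxon_ranksum(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # two-sided p invariant under group swap and monotone transform
  a <- c(1, 5, 3); b <- c(9, 2, 8, 7)
  expect_equal(wilcoxon_ranksum(a, b)$p_value,
               wilcoxon_ranksum(b, a)$p_value)
  expect_equal(wilcoxon_ranksum(a, b)$p_value,
               wilcoxon_ranksum(exp(a), exp(b))$p_value)
  # identical values across both groups
  same <- wilcoxon_ranksum(rep(4, 3), rep(4, 5))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("two-group Kruskal-Wallis H equals the squared rank-sum z", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(12, 1)
  kw <- kruskal_wallis(list(a, b))
  z <- wilcoxon_ranksum(a, b)$z
  expect_equal(kw$H, z^2, tolerance = 1e-10)
  # identical distributions give H = 0
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  # three well-separated groups of five
  kw3 <- kruskal_wallis(list(1:5, 11:15, 21:25))
  expect_lt(kw3$p_value, 0.01)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("published cohort associations are reproduced to print precision", {
  t2 <- load_cohort_summary()
  sp <- spearman_rho(t2$clonality, t2$gsm)  # pairwise-complete: 14 tumours
  expect_equal(sp$n, 14)
  expect_equal(round(sp$rho, 2), 0.83)
  expect_equal(round(sp$p_value, 4), 2e-04)

  pta <- t2$stage == "pTa"
  p_gsm <- wilcoxon_ranksum(t2$gsm[pta], t2$gsm[!pta])
  p_cnv <- wilcoxon_ranksum(t2$cnv_pct[pta], t2$cnv_pct[!pta])
  p_clon <- wilcoxon_ranksum(t2$clonality[pta], t2$clonality[!pta])
  expect_equal(round(p_gsm$p_value, 4), 0.0047)
  expect_equal(round(p_gsm$z, 3), -2.828)   # complete separation
  expect_equal(round(p_cnv$p_value, 4), 0.0046)  # 14/14 tie correction
  expect_equal(round(p_clon$p_value, 4), 0.0060)

  # grade associations (G1-2 vs G3)
  g3 <- t2$grade == "G3"
  expect_equal(round(wilcoxon_ranksum(t2$gsm[!g3], t2$gsm[g3])$p_value, 4),
               0.0041)
  expect_equal(round(wilcoxon_ranksum(t2$cnv_pct[!g3],
                                      t2$cnv_pct[g3])$p_value, 4), 0.0062)
  expect_equal(round(wilcoxon_ranksum(t2$clonality[!g3],
                                      t2$clonality[g3])$p_value, 4), 0.0082)
})

test_that("association screen routes tests and reports untestable pairs", {
  t2 <- load_cohort_summary()
  res <- association_screen(
    t2, burden_vars = c("gsm", "clonality"),
    factors = c("stage", "age", "sex"),
    pooling = list(stage = list("pTa", c("pT1", "pT2"))))
  expect_equal(nrow(res), 6)
  expect_equal(res$test[res$factor == "stage"], rep("wilcoxon", 2))
  expect_equal(res$test[res$factor == "age"], rep("spearman", 2))
  # single-level factor is untestable, not dropped
  t2$site <- "bladder"
  res2 <- association_screen(t2, "gsm", "site")
  expect_match(res2$note, "untestable")
  expect_true(is.na(res2$p_value))
  # BH option appends q-values
  res3 <- association_screen(t2, "gsm", c("stage", "age"),
                             pooling = list(stage = list("pTa",
                                                         c("pT1", "pT2"))),
                             adjust = "BH")
  expect_true("q_value" %in% names(res3))
  expect_true(all(res3$q_value >= res3$p_value))
})

test_that("screen p-values are uniform under permutation of burden", {
  t2 <- load_cohort_summary()
  set.seed(7)
  ps <- replicate(400, {
    perm <- t2
    perm$gsm <- sample(perm$gsm)
    association_screen(perm, "gsm", "stage",
                       pooling = list(stage = list("pTa",
                                                   c("pT1", "pT2"))))$p_value
  })
  # rank-based p at n=14 is discrete; KS against uniform is approximate
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
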