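test_that("PANAS scoring sums the designated items and respects bounds", {
  expect_equal(score_panas(flat_record(1))$pa_total, 10)
  expect_equal(score_panas(flat_record(1))$na_total, 10)
  expect_equal(score_panas(flat_record(5))$pa_total, 50)
  expect_equal(score_panas(flat_record(5))$na_total, 50)

  rec <- flat_record(2)
  rec$items[panas_items()$pa] <- 3L
  s <- score_panas(rec)
  expect_equal(s$pa_total, 30)
  expect_equal(s$na_total, 20)

  # permutation invariance over item order
  rec2 <- rec
  rec2$items <- rec2$items[sample(names(rec2$items))]
  expect_equal(score_panas(rec2)$pa_total, 30)

  bad <- flat_record(3)
  bad$items <- bad$items[-match("proud", names(bad$items))]
  expect_error(score_panas(bad), "proud")
  bad2 <- flat_record(3)
  bad2$items["alert"] <- 6L
  expect_error(score_panas(bad2), "alert")
})

test_that("positivity ratio matches the flourishing benchmarks", {
  expect_equal(positivity_ratio(29.28, 16.75), 1.75)
  expect_equal(positivity_ratio(36.28, 12.09), 3.00)
  expect_equal(positivity_ratio(4.2, 4.2), 1.00)
  expect_error(positivity_ratio(30, 0), "positive")
  expect_error(positivity_ratio(30, -2), "positive")
})

test_that("the affect LMM recovers configured shifts within 2 SE", {
  hits <- t(vapply(1:8, function(k) {
    sc <- score_panas_cohort(simulate_panas_cohort(
      cohort_config(n_subjects = 33, seed = 700 + k)))
    l <- suppressMessages(fit_affect_lmm(sc))$contrasts
    pa <- l[l$affect == "positive", ]
    na <- l[l$affect == "negative", ]
    c(abs(pa$MD - 7) < 2 * pa$SE && pa$MD > 0,
      abs(na$MD + 4.66) < 2 * na$SE && na$MD < 0)
  }, logical(2)))
  expect_gte(mean(hits[, 1]), 0.75)
  expect_gte(mean(hits[, 2]), 0.75)
})

test_that("LRT is ~0 without subject variance and shift-invariant", {
  set.seed(11)
  n <- 24
  scores <- data.frame(
    subject = rep(sprintf("s%02d", 1:n), 2),
    condition = rep(c("pre", "post"), each = n),
    pa_total = round(rnorm(2 * n, 30, 3)),
    na_total = round(rnorm(2 * n, 17, 3)))
  fit <- suppressMessages(fit_affect_lmm(scores))
  expect_lt(fit$lrt$statistic, 3.84)
  expect_gt(fit$lrt$p, 0.05)
  expect_gte(fit$lrt$statistic, 0)
  expect_gte(fit$var_share, 0)
  expect_lte(fit$var_share, 1)

  shifted <- scores
  shifted$pa_total <- shifted$pa_total + 10
  shifted$na_total <- shifted$na_total + 10
  fit2 <- suppressMessages(fit_affect_lmm(shifted))
  expect_equal(fit$lrt$statistic, fit2$lrt$statistic, tolerance = 1e-6)
})

test_that("LMM interaction stays null under within-subject label permutation", {
  ps <- vapply(1:30, function(k) {
    set.seed(800 + k)
    n <- 20
    base <- rnorm(n, 30, 4)
    scores <- data.frame(
      subject = rep(sprintf("s%02d", 1:n), 2),
      condition = rep(sample(c("pre", "post")), each = n),
      pa_total = round(c(base + rnorm(n, 0, 2), base + rnorm(n, 0, 2))),
      na_total = round(rnorm(2 * n, 17, 3)))
    l <- suppressMessages(fit_affect_lmm(scores))
    l$anova$p[l$anova$effect == "affect:condition"]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("item shift tests band evidence and handle identical inputs", {
  expect_equal(bf_evidence_class(c(0.5, 5, 20, 45, 150)),
               c("anecdotal", "moderate", "strong", "very strong",
                 "decisive"))
  # bands partition (0, Inf): boundary values fall in exactly one class
  expect_equal(bf_evidence_class(c(3, 10, 30, 100)),
               c("anecdotal", "moderate", "strong", "very strong"))

  cc <- cohort_config(n_subjects = 33, seed = 21)
  recs <- simulate_panas_cohort(cc)
  pre <- recs[grepl("_pre$", names(recs))]
  post <- recs[grepl("_post$", names(recs))]
  tab <- item_shift_tests(pre, post)
  expect_equal(nrow(tab), 20)
  # the planted shifted items carry the strongest evidence
  up <- tab[tab$item %in% c("active", "alert", "attentive"), ]
  expect_true(all(up$bf10 > 10))
  expect_true(all(tab$p >= 0), all(tab$p <= 1))

  ident <- item_shift_tests(pre, pre)
  expect_true(all(ident$p == 1))
  expect_true(all(ident$bf10 < 1))
})

test_that("JZS and Pearson Bayes factors match independent oracle values", {
  # frozen from an independent numerical implementation of the same
  # default priors (Cauchy sqrt(2)/2; stretched beta width 1)
  expect_equal(bf_ttest(3.464, 3), 2.01133, tolerance = 1e-3)
  expect_equal(bf_ttest(2.5, 20), 2.70229, tolerance = 1e-3)
  expect_equal(bf_ttest(0, 31), 0.191568, tolerance = 1e-3)
  expect_equal(bf_ttest(4.83, 34), 746.574, tolerance = 1e-3)
  expect_equal(bf_pearson(0.48, 33), 9.95082, tolerance = 1e-3)
  expect_equal(bf_pearson(0.45, 31), 4.87287, tolerance = 1e-3)
  expect_equal(bf_pearson(-0.27, 33), 0.655058, tolerance = 1e-3)
})

test_that("correlations report r, CI and BF and reject degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  out <- affect_correlation(x, 2 * x + 1)
  expect_equal(out$r, 1)
  out2 <- affect_correlation(x, -x)
  expect_equal(out2$r, -1)
  expect_error(affect_correlation(x, rep(2, 5)), "variance")
  expect_error(affect_correlation(1:3, 3:1), ">= 4")

  hits <- vapply(1:40, function(k) {
    set.seed(900 + k)
    z <- rnorm(33); e <- rnorm(33)
    x <- z; y <- 0.48 * z + sqrt(1 - 0.48^2) * e
    abs(affect_correlation(x, y)$r - 0.48) < 0.30
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Welch test handles identical, hand-computed and null cases", {
  g <- c(4, 5, 6, 7)
  out <- welch_group_test(g, g)
  expect_equal(out$t, 0)
  expect_equal(out$MD, 0)
  expect_equal(welch_group_test(c(1, 2, 3), c(2, 3, 4))$MD, -1)
  expect_error(welch_group_test(1, c(2, 3)), ">= 2")

  fp <- vapply(1:100, function(k) {
    set.seed(1000 + k)
    welch_group_test(rnorm(14), rnorm(19))$p < 0.05
  }, logical(1))
  expect_lte(mean(fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("paired effect sizes are exact on hand cases", {
  base <- c(0, 0, 0)
  out <- paired_effect(base, c(1, 2, 3))
  expect_equal(out$t, 3.464, tolerance = 1e-3)
  expect_equal(out$cohen_d, 2)
  expect_equal(out$MD, 2)

  # benchmark heart-rate effect: t = 4.83 at n = 34 gives d = 0.84 with
  # noncentral-t 95% CI [0.44, 1.23] (to printed rounding)
  set.seed(12)
  z <- rnorm(34)
  d34 <- (z - mean(z)) / sd(z) + 4.83 / sqrt(34)  # mean/sd fixed => t = 4.83
  hr <- paired_effect(rep(0, 34), d34)
  expect_equal(hr$t, 4.83, tolerance = 1e-6)
  expect_equal(hr$cohen_d, 0.84, tolerance = 0.02)
  expect_equal(unname(hr$d_ci), c(0.44, 1.23), tolerance = 0.02)

  zero <- paired_effect(c(1, 2, 3), c(1, 2, 3))
  expect_equal(zero$t, 0)
  expect_equal(zero$cohen_d, 0)
  expect_equal(zero$p, 1)
  expect_error(paired_effect(1:2, 2:3), ">= 3")

  hits <- vapply(1:40, function(k) {
    set.seed(1100 + k)
    d <- rnorm(34, 0.84, 1)
    abs(paired_effect(rep(0, 34), d)$cohen_d - 0.84) < 0.35
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("interval means bin uniformly sampled traces", {
  const <- data.frame(time = 0:59, value = rep(3.3, 60))
  m <- interval_means(const)
  expect_equal(nrow(m), 6)
  expect_true(all(m$mean == 3.3))

  short <- data.frame(time = 0:24, value = rnorm(25))
  expect_equal(nrow(interval_means(short)), 2)

  ramp <- data.frame(time = 0:29, value = 2 * (0:29) + 1)
  mr <- interval_means(ramp)
  # mean of an arithmetic sequence = value at the midpoint of its times
  expect_equal(mr$mean, 2 * c(4.5, 14.5, 24.5) + 1)
})

test_that("gasp detection requires window coverage", {
  br <- data.frame(time = c(1, 3, 5), volume = c(0.5, 1.2, 0.8))
  expect_equal(inspiratory_gasp(br, 0, trace_end = 10), 1.2)
  expect_error(inspiratory_gasp(br, 0), "cover")
})
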