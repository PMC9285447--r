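test_that("cosine similarity matches closed forms and rejects zero vectors", {
  expect_equal(cosine_sim(c(2, 1, 0), c(2, 1, 0)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), sqrt(2) / 2, tolerance = 1e-5)
  expect_equal(cosine_sim(c(1, 2), c(-1, -2)), -1)
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_sim(c(1, 2), c(1, 2, 3)), "lengths")
})

test_that("score summaries use the sample SD and the 1.96 normal interval", {
  x <- c(0.2, 0.4, 0.3, 0.5, 0.1)
  s <- summarize_scores(x)
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sd(x))
  expect_equal(s$ci_high - s$ci_low, 2 * 1.96 * sd(x) / sqrt(5))
  same <- summarize_scores(rep(0.3, 10))
  expect_equal(same$sd, 0)
  expect_equal(c(same$ci_low, same$ci_high), c(0.3, 0.3))
  expect_error(summarize_scores(0.5), "at least 2")
})

test_that("CI reconstruction reproduces published transfer rows to printed precision", {
  # visual transfer summaries, n = 3423 test items per fold
  visual <- rbind(
    c(0.2343, 0.0411, 0.2329, 0.2357), c(0.2243, 0.0382, 0.2230, 0.2256),
    c(0.2382, 0.0410, 0.2368, 0.2396), c(0.2278, 0.0386, 0.2266, 0.2291),
    c(0.2391, 0.0394, 0.2378, 0.2404), c(0.2243, 0.0399, 0.2229, 0.2256),
    c(0.2320, 0.0431, 0.2306, 0.2335), c(0.2224, 0.0384, 0.2211, 0.2237),
    c(0.2381, 0.0404, 0.2367, 0.2394), c(0.2257, 0.0387, 0.2244, 0.2270),
    c(0.2389, 0.0418, 0.2375, 0.2403), c(0.2228, 0.0384, 0.2216, 0.2241))
  # the published bounds are printed at 4 decimals and the inputs (mean, SD)
  # are themselves rounded, so reconstruction must agree within one unit in
  # the 4th decimal everywhere, and exactly wherever the inputs allow it
  check_rows <- function(rows, n, min_exact) {
    exact <- 0L
    for (i in seq_len(nrow(rows))) {
      ci <- unname(ci_from_summary(rows[i, 1], rows[i, 2], n))
      expect_lt(max(abs(ci - rows[i, 3:4])), 1.01e-4)
      exact <- exact + sum(round(ci, 4) == rows[i, 3:4])
    }
    expect_gte(exact, min_exact)
  }
  # semantic transfer summaries, n = 4922 test items per fold
  semantic <- rbind(
    c(0.5263, 0.0687, 0.5244, 0.5282), c(0.5245, 0.0654, 0.5227, 0.5263),
    c(0.5253, 0.0683, 0.5234, 0.5272), c(0.5241, 0.0665, 0.5222, 0.5259),
    c(0.5264, 0.0690, 0.5245, 0.5284), c(0.5237, 0.0675, 0.5218, 0.5256),
    c(0.5214, 0.0742, 0.5193, 0.5234), c(0.5218, 0.0705, 0.5199, 0.5238),
    c(0.5256, 0.0675, 0.5237, 0.5275), c(0.5230, 0.0693, 0.5210, 0.5249),
    c(0.5281, 0.0683, 0.5262, 0.5300), c(0.5227, 0.0701, 0.5207, 0.5246))
  check_rows(visual, 3423, min_exact = 19L)    # 19/24 bounds land exactly
  check_rows(semantic, 4922, min_exact = 18L)  # 18/24 bounds land exactly
  # the Arabic model rows reproduce exactly at 4 decimals
  expect_equal(round(unname(ci_from_summary(0.2343, 0.0411, 3423)), 4),
               c(0.2329, 0.2357))
  expect_equal(round(unname(ci_from_summary(0.5263, 0.0687, 4922)), 4),
               c(0.5244, 0.5282))
})

test_that("paired contrast matches the hand-computed example and t.test", {
  a <- c(0.3, 0.5, 0.7, 0.4)
  b <- c(0.2, 0.4, 0.5, 0.4)
  ct <- paired_contrast(a, b)
  expect_equal(ct$t, 2.4495, tolerance = 1e-3)
  expect_equal(ct$d, 1.2247, tolerance = 1e-3)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(ct$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-10)
})

test_that("paired contrast agrees with the reference t-test on random data", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    a <- rnorm(n, 0.3, 0.1)
    b <- a - rnorm(n, 0.02, 0.08)
    ct <- paired_contrast(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(ct$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(ct$p, ref$p.value, tolerance = 1e-6)
    expect_equal(ct$d, mean(a - b) / sd(a - b), tolerance = 1e-10)
    expect_equal(sign(ct$t), sign(mean(a) - mean(b)))
  }
})

test_that("paired contrast handles degenerate difference spreads", {
  eq <- paired_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(eq$t, eq$p, eq$d), c(0, 1, 0))
  const <- paired_contrast(c(1, 2, 3) + 0.5, c(1, 2, 3))
  expect_true(is.infinite(const$t) && const$t > 0)
  expect_equal(const$p, 0)
})

test_that("McNemar equals the closed form on exhaustive small tables", {
  for (b in 0:6) for (cc in 0:6) {
    if (b + cc == 0) next
    correct_m <- rep(c(TRUE, FALSE, TRUE), c(b, cc, 3))
    correct_b <- rep(c(FALSE, TRUE, TRUE), c(b, cc, 3))
    res <- mcnemar_chisq(correct_m, correct_b)
    expect_equal(res$chi2, (b - cc)^2 / (b + cc), tolerance = 1e-12)
    expect_equal(res$p, pchisq((b - cc)^2 / (b + cc), 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # symmetry: swapping the classifiers leaves chi2 unchanged
    expect_equal(mcnemar_chisq(correct_b, correct_m)$chi2, res$chi2)
  }
})

test_that("McNemar matches the reference implementation and handles b + c = 0", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    if (sum(m & !b) + sum(!m & b) == 0) next
    res <- mcnemar_chisq(m, b)
    ref <- mcnemar.test(table(factor(m, c(FALSE, TRUE)),
                              factor(b, c(FALSE, TRUE))), correct = FALSE)
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(res$p, ref$p.value, tolerance = 1e-6)
  }
  expect_warning(res0 <- mcnemar_chisq(c(TRUE, FALSE), c(TRUE, FALSE)),
                 "no discordant")
  expect_equal(c(res0$chi2, res0$p), c(0, 1))
  expect_equal(mcnemar_chisq(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))$chi2, 0)
})

test_that("classification metrics match the hand-computed example", {
  m <- classification_metrics(c("A", "A", "B", "B", "B"),
                              c("A", "B", "B", "B", "A"), c("A", "B"))
  expect_equal(m$accuracy, 0.6, tolerance = 1e-9)
  # precision A = 1/2, B = 2/3; supports 2 and 3
  expect_equal(m$weighted_precision, 0.4 * 0.5 + 0.6 * 2 / 3, tolerance = 1e-9)
  expect_equal(m$weighted_f1, 0.6, tolerance = 1e-9)
  expect_equal(unname(m$per_class_accuracy), c(0.5, 2 / 3), tolerance = 1e-9)

  perfect <- classification_metrics(c("A", "B", "C"), c("A", "B", "C"),
                                    c("A", "B", "C"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$weighted_precision, 1)
  expect_equal(perfect$weighted_f1, 1)
  expect_true(all(perfect$per_class_accuracy == 1))
})

test_that("support-weighted recall equals accuracy on random label sets", {
  set.seed(11)
  classes <- c("A", "B", "C", "D")
  for (i in 1:20) {
    truth <- sample(classes, 50, replace = TRUE)
    pred <- sample(classes, 50, replace = TRUE)
    m <- classification_metrics(truth, pred, classes)
    rec <- m$per_class_accuracy
    w <- m$support / sum(m$support)
    expect_equal(sum(w * ifelse(is.na(rec), 0, rec)), m$accuracy,
                 tolerance = 1e-12)
  }
})

test_that("a never-predicted class contributes zero precision", {
  m <- classification_metrics(c("A", "A", "B"), c("A", "A", "A"), c("A", "B"))
  expect_equal(unname(m$per_class_accuracy), c(1, 0))
  expect_equal(m$weighted_precision, (2 / 3) * (2 / 3) + (1 / 3) * 0,
               tolerance = 1e-12)
})

test_that("cross-language consistency matches brute-force pair correlations", {
  v <- list(L1 = c(a = 0.9, b = 0.5, c = 0.2),
            L2 = c(a = 0.8, b = 0.6, c = 0.1),
            L3 = c(a = 0.3, b = 0.7, c = 0.5))
  cc <- cross_language_consistency(v)
  manual <- mean(c(cor(v$L1, v$L2), cor(v$L1, v$L3), cor(v$L2, v$L3)))
  expect_equal(cc$mean_pairwise_r, manual, tolerance = 1e-9)
  expect_equal(unname(cc$per_class_mean),
               unname(colMeans(do.call(rbind, v))), tolerance = 1e-12)

  ident <- cross_language_consistency(list(L1 = c(a = 1, b = 2, c = 3, d = 4) / 4,
                                           L2 = c(a = 1, b = 2, c = 3, d = 4) / 4))
  expect_equal(ident$mean_pairwise_r, 1)
  rev2 <- cross_language_consistency(list(L1 = c(a = 1, b = 2, c = 3, d = 4) / 4,
                                          L2 = c(a = 4, b = 3, c = 2, d = 1) / 4))
  expect_equal(rev2$mean_pairwise_r, -1)
})

test_that("zero-variance languages are excluded with a flag", {
  v <- list(L1 = c(a = 0.5, b = 0.5), L2 = c(a = 0.9, b = 0.1),
            L3 = c(a = 0.8, b = 0.3))
  expect_warning(cc <- cross_language_consistency(v), "zero-variance")
  expect_equal(cc$excluded, "L1")
  expect_equal(nrow(cc$pairwise), 1L)
})
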