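test_that("split sizes use half-up rounding at the documented ratios", {
  ids <- function(n) sprintf("c%05d", seq_len(n))
  s <- split_concepts(ids(1161), ratio = 0.8, seed = 1)
  expect_equal(length(s$train_ids), 929L)
  expect_equal(length(s$test_ids), 232L)
  s <- split_concepts(ids(24612), ratio = 0.8, seed = 1)
  expect_equal(length(s$train_ids), 19690L)
  expect_equal(length(s$test_ids), 4922L)
  s <- split_concepts(ids(24246), ratio = 0.5, seed = 1)
  expect_equal(length(s$train_ids), 12123L)
  s <- split_concepts(ids(10), ratio = 0.5, seed = 1)
  expect_equal(length(s$train_ids), 5L)
  expect_error(split_concepts(ids(10), ratio = 1), "between 0 and 1")
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  ids <- sprintf("c%03d", 1:57)
  s1 <- split_concepts(ids, 0.8, seed = 4)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_setequal(c(s1$train_ids, s1$test_ids), ids)
  expect_identical(s1, split_concepts(ids, 0.8, seed = 4))
  expect_false(identical(s1$train_ids, split_concepts(ids, 0.8, seed = 5)$train_ids))
})

test_that("conditions hold out a whole language and pass disjointness", {
  lex <- tiny_lexicon(n = 20)
  split <- split_concepts(lex$concepts$ids, 0.8, seed = 2)
  cond <- build_condition(lex, lex$visual_targets, split, heldout = "L2")
  expect_equal(sort(unique(cond$train_prov$language_id)), c("L1", "L3"))
  expect_equal(unique(cond$test_prov$language_id), "L2")
  expect_equal(nrow(cond$train_targets), 16 * 2)
  expect_equal(nrow(cond$test_targets), 4)
  expect_true(verify_disjoint(cond)$pass)
  expect_error(build_condition(lex, lex$visual_targets, split, heldout = "L9"),
               "unknown")
})

test_that("mutated conditions are caught by the disjointness check", {
  lex <- tiny_lexicon(n = 20)
  split <- split_concepts(lex$concepts$ids, 0.8, seed = 2)
  cond <- build_condition(lex, lex$visual_targets, split, heldout = "L2")

  leak <- cond
  leak$train_prov$concept_id[1] <- leak$test_prov$concept_id[1]
  rep1 <- verify_disjoint(leak)
  expect_false(rep1$pass)
  expect_match(rep1$violations, leak$test_prov$concept_id[1], all = FALSE)

  fam <- cond
  fam$train_prov$family_id[3] <- cond$heldout_family
  rep2 <- verify_disjoint(fam)
  expect_false(rep2$pass)
  expect_match(rep2$violations, "held-out family", all = FALSE)

  lng <- cond
  lng$test_prov$language_id[2] <- "L1"
  expect_false(verify_disjoint(lng)$pass)
})

test_that("target shuffling permutes pairings but preserves the multiset", {
  lex <- tiny_lexicon(n = 20)
  split <- split_concepts(lex$concepts$ids, 0.8, seed = 2)
  cond <- build_condition(lex, lex$visual_targets, split, heldout = "L1")
  bl <- shuffle_targets(cond, seed = 9)
  expect_identical(bl$train$x, cond$train$x)  # inputs untouched
  expect_equal(bl$train_targets[order(bl$permutation), ], cond$train_targets)
  expect_identical(shuffle_targets(cond, seed = 9)$permutation, bl$permutation)
  # explicit identity permutation leaves pairs unchanged
  idp <- shuffle_targets(cond, permutation = seq_len(nrow(cond$train_targets)))
  expect_equal(idp$train_targets, cond$train_targets)
})

test_that("shuffling is uniform over permutations", {
  # 1000 shuffles of 4 items: each of the 24 permutations should occur with
  # frequency 1/24 within 3 binomial standard errors
  lex <- tiny_lexicon(n = 5)
  split <- split_concepts(lex$concepts$ids, 0.8, seed = 2)
  cond <- build_condition(lex, lex$visual_targets, split, heldout = "L1")
  # restrict to 4 training pairs
  cond$train <- iconotrans:::batch_subset(cond$train, 1:4)
  cond$train_targets <- cond$train_targets[1:4, ]
  cond$train_prov <- cond$train_prov[1:4, ]
  seen <- vapply(1:1000, function(s)
    paste(shuffle_targets(cond, seed = s)$permutation, collapse = ""),
    character(1))
  freq <- table(seen) / 1000
  expect_equal(length(freq), 24L)
  se <- sqrt((1 / 24) * (23 / 24) / 1000)
  expect_true(all(abs(freq - 1 / 24) <= 3 * se))
})

test_that("oversampling raises every class to the majority count", {
  classes <- rep(c("A", "B", "C"), c(5, 2, 3))
  idx <- oversample_classes(classes, seed = 3)
  expect_equal(as.numeric(table(classes[idx])), c(5, 5, 5))
  expect_true(all(seq_along(classes) %in% idx))
  # balanced input: unchanged
  expect_equal(oversample_classes(rep(c("A", "B"), each = 4), seed = 1), 1:8)
  # single class: unchanged
  expect_equal(oversample_classes(rep("A", 6), seed = 1), 1:6)
  expect_identical(oversample_classes(classes, seed = 3), idx)
})

test_that("oversampled conditions balance training but never touch the test set", {
  lex <- tiny_lexicon(n = 30, gamma = 0.5, seed = 10)
  scheme <- default_class_scheme(3)
  raw <- paste0("c", lex$concepts$class)
  targets <- do.call(rbind, lapply(raw, encode_class, scheme = scheme))
  rownames(targets) <- lex$concepts$ids
  classes <- stats::setNames(raw, lex$concepts$ids)
  split <- split_concepts(lex$concepts$ids, 0.5, seed = 2)
  plain <- build_condition(lex, targets, split, heldout = "L1", classes = classes)
  over <- build_condition(lex, targets, split, heldout = "L1", classes = classes,
                          oversample = TRUE, oversample_seed = 6)
  # per language, every class reaches the per-language majority count
  for (lang in unique(over$train_prov$language_id)) {
    cl <- over$train_classes[over$train_prov$language_id == lang]
    expect_true(all(table(cl) == max(table(cl))))
  }
  expect_identical(over$test_prov, plain$test_prov)
  expect_identical(over$test_targets, plain$test_targets)
  expect_true(verify_disjoint(over)$pass)
})
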