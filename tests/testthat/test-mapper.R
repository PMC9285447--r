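test_that("config invariants tie the loss to the output activation", {
  expect_error(mapper_config(10, 5, "relu", "categorical_cross_entropy"),
               "softmax")
  expect_error(mapper_config(10, 5, "softmax", "negative_cosine"),
               "relu or linear")
  cfg <- mapper_config(10, 5)
  expect_equal(cfg$dropout, 0.2)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$epochs, 1L)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  f <- 3L; h <- 4L; o <- 5L; b <- 3L
  params <- iconotrans:::lstm_init(f, h, o)
  x <- array(rnorm(b * 15 * f), c(b, 15, f))
  mask <- matrix(FALSE, b, 15)
  mask[1, 1:4] <- TRUE; mask[2, 1:2] <- TRUE; mask[3, 1:7] <- TRUE
  for (i in 1:b) x[i, !mask[i, ], ] <- 0
  for (loss in c("negative_cosine", "categorical_cross_entropy")) {
    act <- if (loss == "negative_cosine") "relu" else "softmax"
    targets <- if (loss == "negative_cosine") {
      matrix(abs(rnorm(b * o)), b, o)
    } else {
      tm <- matrix(0, b, o); tm[cbind(1:b, sample(o, b, TRUE))] <- 1; tm
    }
    lossfun <- function(p) {
      fwd <- iconotrans:::lstm_forward(p, x, mask)
      pre <- fwd$h %*% p$Wy + matrix(p$by, b, o, byrow = TRUE)
      y <- iconotrans:::apply_activation(pre, act)
      iconotrans:::loss_grad(pre, y, targets, loss, act)$loss
    }
    fwd <- iconotrans:::lstm_forward(params, x, mask, keep_cache = TRUE)
    pre <- fwd$h %*% params$Wy + matrix(params$by, b, o, byrow = TRUE)
    y <- iconotrans:::apply_activation(pre, act)
    lg <- iconotrans:::loss_grad(pre, y, targets, loss, act)
    grads <- iconotrans:::lstm_backward(params, fwd,
                                        tcrossprod(lg$dpre, params$Wy))
    grads$Wy <- crossprod(fwd$h, lg$dpre)
    grads$by <- colSums(lg$dpre)
    eps <- 1e-6
    for (nm in names(grads)) {
      idx <- sample(length(params[[nm]]), min(12, length(params[[nm]])))
      for (i in idx) {
        pp <- params
        pp[[nm]][i] <- params[[nm]][i] + eps
        up <- lossfun(pp)
        pp[[nm]][i] <- params[[nm]][i] - eps
        dn <- lossfun(pp)
        num <- (up - dn) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("a regressor drives predictions toward a shared unit target", {
  tab <- make_feature_table(10, 6, seed = 1)
  set.seed(3)
  words <- encode_words(replicate(40, paste(
    sample(phones(tab), sample(2:6, 1), replace = TRUE), collapse = " ")), tab)
  target <- rep(1, 8) / sqrt(8)
  targets <- matrix(target, 40, 8, byrow = TRUE)
  cfg <- tiny_mapper(8, hidden = 8L, epochs = 40L, dropout = 0,
                     recurrent_dropout = 0)
  m <- train_regressor(words, targets, cfg)
  preds <- predict(m, words)
  cosines <- vapply(seq_len(40), function(i)
    cosine_sim(preds[i, ], target), numeric(1))
  expect_gt(mean(cosines), 0.99)
  # reported training metric equals external recomputation
  expect_equal(m$log$train_metric, mean(cosines), tolerance = 1e-5)
})

test_that("a classifier separates classes keyed to the first phone", {
  # two classes fully determined by the word-initial phone
  tab <- phone_feature_table(rbind(p = c(1, 1, 0), q = c(-1, -1, 0),
                                   x = c(0, 1, -1)))
  set.seed(4)
  first <- sample(c("p", "q"), 60, replace = TRUE)
  seqs <- vapply(first, function(ph) paste(
    c(ph, sample("x", sample(0:3, 1), replace = TRUE)), collapse = " "),
    character(1))
  words <- encode_words(unname(seqs), tab)
  onehot <- cbind(first == "p", first == "q") * 1
  cfg <- tiny_mapper(2, loss = "categorical_cross_entropy",
                     activation = "softmax", hidden = 6L, epochs = 30L,
                     dropout = 0, recurrent_dropout = 0)
  m <- train_classifier(words, onehot, cfg)
  preds <- predict(m, words)
  expect_gt(mean(max.col(preds) == max.col(onehot)), 0.95)
  expect_equal(rowSums(preds), rep(1, 60), tolerance = 1e-6)
})

test_that("training is bitwise deterministic given the seed", {
  lex <- tiny_lexicon(n = 15, beta = 0.5)
  split <- split_concepts(lex$concepts$ids, 0.8, seed = 1)
  cond <- build_condition(lex, lex$visual_targets, split, heldout = "L1")
  cfg <- tiny_mapper(ncol(lex$visual_targets), epochs = 2L)
  m1 <- train_regressor(cond$train, cond$train_targets, cfg)
  m2 <- train_regressor(cond$train, cond$train_targets, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, cond$test), predict(m2, cond$test))
  m3 <- train_regressor(cond$train, cond$train_targets,
                        tiny_mapper(ncol(lex$visual_targets), epochs = 2L,
                                    seed = 99L))
  expect_false(identical(m1$params, m3$params))
})

test_that("predictions ignore padding beyond the mask", {
  tab <- toy_table()
  cfg <- tiny_mapper(3, hidden = 5L, epochs = 1L)
  set.seed(8)
  words <- encode_words(c("a b ts", "o o", "ab a o b"), tab)
  m <- train_regressor(words, matrix(abs(rnorm(9)), 3, 3), cfg)
  w <- encode_word(c("a", "b"), tab)
  # corrupt a masked row: prediction must be bit-identical because the
  # recurrence carries the state through masked steps unchanged
  w_dirty <- w
  w_dirty$matrix[10, ] <- 99
  expect_identical(predict(m, w), predict(m, w_dirty))
})

test_that("batch composition does not change predictions beyond 1e-5", {
  tab <- toy_table()
  set.seed(9)
  words <- encode_words(replicate(20, paste(
    sample(phones(tab), sample(1:6, 1), replace = TRUE), collapse = " ")), tab)
  cfg <- tiny_mapper(3, hidden = 5L, epochs = 1L)
  m <- train_regressor(words, matrix(abs(rnorm(60)), 20, 3), cfg)
  all_at_once <- predict(m, words)
  one_by_one <- do.call(rbind, lapply(seq_len(20), function(i)
    predict(m, iconotrans:::batch_subset(words, i))))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-5)
  chunked <- predict(m, words, batch_size = 7L)
  expect_equal(all_at_once, chunked, tolerance = 1e-5)
})

test_that("relu outputs are nonnegative and empty input yields empty output", {
  tab <- toy_table()
  set.seed(10)
  words <- encode_words(replicate(10, paste(
    sample(phones(tab), 3, replace = TRUE), collapse = " ")), tab)
  cfg <- tiny_mapper(4, hidden = 4L, epochs = 1L)
  m <- train_regressor(words, matrix(abs(rnorm(40)), 10, 4), cfg)
  expect_true(all(predict(m, words) >= 0))
  expect_equal(nrow(predict(m, list())), 0L)
  # dimension mismatches are rejected
  other <- encode_words("p1 p2", make_feature_table(5, 7, seed = 1))
  expect_error(predict(m, other), "features")
  expect_error(train_regressor(words, matrix(1, 10, 3), cfg), "dimensions")
})

test_that("checkpoints restore a model that predicts identically", {
  tab <- toy_table()
  set.seed(12)
  words <- encode_words(replicate(8, paste(
    sample(phones(tab), 3, replace = TRUE), collapse = " ")), tab)
  m <- train_regressor(words, matrix(abs(rnorm(24)), 8, 3),
                       tiny_mapper(3, hidden = 4L, epochs = 1L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_mapping_model(m, path)
  back <- load_mapping_model(path)
  expect_identical(predict(back, words), predict(m, words))
  expect_identical(back$config, m$config)
})
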