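test_that("the stratified split is disjoint, exhaustive, and seed-deterministic", {
  tab <- toy_table(n_per_class = 25, seed = 40)
  tab$id <- seq_len(nrow(tab))
  split <- split_dataset(tab, test_fraction = 0.2, seed = 5)
  expect_equal(nrow(split$train), 80)
  expect_equal(nrow(split$test), 20)
  expect_equal(unname(table(split$test$label)), rep(5L, 4),
               ignore_attr = TRUE)
  expect_length(intersect(split$train$id, split$test$id), 0)
  expect_setequal(c(split$train$id, split$test$id), tab$id)
  again <- split_dataset(tab, test_fraction = 0.2, seed = 5)
  expect_identical(split$test$id, again$test$id)
  expect_false(identical(split$test$id,
                         split_dataset(tab, 0.2, seed = 6)$test$id))
  expect_error(split_dataset(tab[c(1, 26, 51, 76, 2), ], 0.2, 1),
               class = "respscreen_contract_error")
})

test_that("oversampling balances class counts without touching balanced data", {
  tab <- toy_table(n_per_class = 5, seed = 41)
  skewed <- tab[c(1:5, 6, 11:13, 16:20), ]  # counts 5, 1, 3, 5
  bal <- balance_classes(skewed, seed = 2)
  expect_equal(unname(table(bal$label)), rep(5L, 4), ignore_attr = TRUE)
  # oversampled rows are copies of existing rows
  expect_true(all(bal$f1 %in% skewed$f1))
  expect_identical(balance_classes(skewed, seed = 2), bal)
  balanced <- balance_classes(tab, seed = 3)
  expect_equal(sort(balanced$f1), sort(tab$f1))
  expect_error(balance_classes(tab[0, ], 1),
               class = "respscreen_contract_error")
})

test_that("training separates a linearly separable toy problem and is seeded", {
  tab <- toy_table(n_per_class = 4, sd = 0.2, seed = 42)
  cfg <- model_config(n_hidden = 16, max_epochs = 1000, dropout_rate = 0.2,
                      batch_size = 8, seed = 1)
  for (seed in 1:5) {
    cfg$seed <- seed
    model <- train_classifier(tab, cfg, features = c("f1", "f2"))
    expect_equal(mean(predict_classes(model, tab) == tab$label), 1)
  }
  m1 <- train_classifier(tab, cfg, features = c("f1", "f2"))
  m2 <- train_classifier(tab, cfg, features = c("f1", "f2"))
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
})

test_that("an overwhelming weight penalty drives weights to zero", {
  tab <- toy_table(n_per_class = 4, seed = 43)
  cfg <- model_config(n_hidden = 8, max_epochs = 1000, dropout_rate = 0,
                      l2_penalty = 1e6, batch_size = 4, learning_rate = 5e-3,
                      seed = 7)
  model <- train_classifier(tab, cfg, features = c("f1", "f2"))
  expect_lt(max(abs(model$w1)), 1e-2)
  expect_lt(max(abs(model$w2)), 1e-2)
})

test_that("predicted probabilities are a proper simplex and pure-function stable", {
  tab <- toy_table(n_per_class = 6, seed = 44)
  model <- train_classifier(tab, fast_config(seed = 3),
                            features = c("f1", "f2"))
  newx <- withr::with_seed(45, matrix(rnorm(40), ncol = 2))
  p <- predict_proba(model, newx)
  expect_equal(dim(p), c(20, 4))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict_proba(model, newx), p)
  expect_equal(predict_proba(model, newx[1, ]), p[1, , drop = FALSE],
               tolerance = 1e-12)
  expect_error(predict_proba(model, newx[, 1, drop = FALSE]),
               class = "respscreen_contract_error")
  expect_error(train_classifier(transform(tab, f1 = Inf), fast_config(),
                                features = c("f1", "f2")),
               class = "respscreen_contract_error")
})

test_that("the hidden-node sweep reports one row per count and the smallest-gap winner", {
  tab <- toy_table(n_per_class = 12, seed = 46)
  sweep_res <- hidden_node_sweep(tab, node_counts = c(8L, 16L, 32L),
                                 config = fast_config(seed = 4),
                                 features = c("f1", "f2"))
  expect_equal(nrow(sweep_res), 3)
  expect_equal(sweep_res$n_hidden, c(8L, 16L, 32L))
  expect_true(all(sweep_res$train_accuracy >= 0 &
                    sweep_res$train_accuracy <= 1))
  expect_true(all(sweep_res$test_accuracy >= 0 &
                    sweep_res$test_accuracy <= 1))
  # recompute the selection rule from the returned table
  top <- sweep_res$test_accuracy >= max(sweep_res$test_accuracy) - 0.01
  cand <- sweep_res[top, ]
  cand <- cand[order(cand$gap, cand$n_hidden), ]
  expect_identical(attr(sweep_res, "selected"), cand$n_hidden[1])
  expect_error(hidden_node_sweep(tab, integer(0)),
               class = "respscreen_contract_error")
})

test_that("model archives restore predictions exactly", {
  tab <- toy_table(n_per_class = 6, seed = 47)
  model <- train_classifier(tab, fast_config(seed = 9),
                            features = c("f1", "f2"))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$features, model$features)
  expect_identical(back$classes, model$classes)
  newx <- withr::with_seed(48, matrix(rnorm(20), ncol = 2))
  expect_equal(predict_proba(back, newx), predict_proba(model, newx),
               tolerance = 1e-12)
})
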