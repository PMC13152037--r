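# Fold construction, loss, learning-rate schedule, and the training loop.

test_that("stratified folds partition 2610 samples into five folds of 522", {
  labels <- rep(cough_classes(), each = 522)
  plan <- make_folds(seq_len(2610), labels, k = 5, seed = 61)
  sizes <- tabulate(plan$assignment, 5)
  expect_identical(sizes, rep(522L, 5))
  # class balance within one sample per fold
  for (cl in cough_classes()) {
    per_fold <- tabulate(plan$assignment[labels == cl], 5)
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("folds are an exact partition and near-equal for awkward sizes", {
  set.seed(62)
  labels <- sample(cough_classes(), 103, replace = TRUE)
  plan <- make_folds(seq_len(103), labels, k = 5, seed = 63)
  expect_identical(sort(as.integer(names(table(plan$assignment)))), 1:5)
  expect_identical(length(plan$assignment), 103L)       # every id exactly once
  expect_lte(diff(range(tabulate(plan$assignment, 5))), 1)
  for (cl in unique(labels)) {
    expect_lte(diff(range(tabulate(plan$assignment[labels == cl], 5))), 1)
  }
})

test_that("fold plans are seed-deterministic and seed-sensitive", {
  labels <- rep(cough_classes(), each = 20)
  p1 <- make_folds(seq_len(100), labels, k = 5, seed = 64)
  p2 <- make_folds(seq_len(100), labels, k = 5, seed = 64)
  expect_identical(p1$assignment, p2$assignment)
  others <- vapply(1:10, function(s) {
    identical(make_folds(seq_len(100), labels, k = 5, seed = 64 + s)$assignment,
              p1$assignment)
  }, logical(1))
  expect_false(any(others))
  expect_error(make_folds(1:3, labels[1:3], k = 5), "folds")
})

test_that("cross-entropy equals -log q(true class)", {
  expect_equal(cross_entropy_loss(c(0, 1, 0, 0, 0), c(0, 1, 0, 0, 0)), 0)
  expect_equal(cross_entropy_loss(3, rep(0.2, 5)), log(5))
  expect_equal(cross_entropy_loss(c(0, 1, 0, 0, 0), c(0.1, 0.6, 0.1, 0.1, 0.1)),
               -log(0.6))
  expect_warning(z <- cross_entropy_loss(1, c(0, 0.5, 0.5, 0, 0)), "clamped")
  expect_equal(z, -log(1e-12))
})

test_that("the learning rate follows 0.001 * 0.1^floor(e/7)", {
  cfg <- train_config()
  e <- 0:49
  expect_equal(vapply(e, lr_at_epoch, numeric(1), cfg = cfg),
               0.001 * 0.1^(e %/% 7))
  expect_equal(lr_at_epoch(6, cfg), 0.001)
  expect_equal(lr_at_epoch(7, cfg), 0.0001)
})

test_that("training records history, lr schedule, and a reloadable best model", {
  st <- small_trained()
  fs <- small_feature_set()
  expect_identical(nrow(st$history), 2L)
  expect_equal(st$history$lr, c(0.001, 0.001))
  expect_true(all(is.finite(st$history$train_loss)))
  # best checkpoint reproduces its recorded validation accuracy exactly
  pred <- predict_classes(st$model, fs$inputs[, , st$va, drop = FALSE])
  expect_identical(mean(pred$class == fs$labels[st$va]), st$best_val_acc)
  # and survives a save/load roundtrip
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st$model, p)
  pred2 <- predict_classes(load_checkpoint(p), fs$inputs[, , st$va, drop = FALSE])
  expect_identical(pred2$class, pred$class)
})

test_that("a missing class in the training split is rejected", {
  fs <- small_feature_set()
  keep <- fs$labels != 1
  expect_error(
    train_model(fs$inputs[, , keep, drop = FALSE], fs$labels[keep],
                fs$inputs, fs$labels,
                cfg = train_config(epochs = 1),
                net_cfg = network_config(input_size = 32)),
    "missing")
})

test_that("the network can overfit a single batch", {
  # capacity/optimization sanity: 50 steps on 8 images drives loss below 0.1
  ok <- 0
  for (s in 1:5) {
    set.seed(700 + s)
    x <- array(runif(32 * 32 * 8), c(32, 32, 8))
    y <- rep(1:4, 2)
    res <- train_model(x, y, x, y,
                       cfg = train_config(epochs = 50, batch_size = 8,
                                          step_size = 1000, seed = 800 + s),
                       net_cfg = network_config(input_size = 32, num_classes = 4))
    if (min(res$history$train_loss) < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("predictions are valid distributions and order-equivariant", {
  st <- small_trained()
  fs <- small_feature_set()
  x <- fs$inputs[, , st$va[1:10], drop = FALSE]
  pr <- predict_classes(st$model, x)
  expect_true(all(abs(colSums(pr$prob) - 1) < 1e-6))
  perm <- c(4, 1, 10, 2, 7, 3, 9, 5, 8, 6)
  pr2 <- predict_classes(st$model, x[, , perm, drop = FALSE])
  expect_identical(pr2$class, pr$class[perm])
  expect_equal(pr2$prob, pr$prob[, perm])
  # arg-max ties break toward the lowest class index
  expect_identical(which.max(rep(0.2, 5)), 1L)
})

test_that("cross-validation validates every sample exactly once", {
  fs <- small_feature_set()
  cv <- crossval_train(fs$inputs, fs$labels, k = 2,
                       cfg = train_config(epochs = 1, seed = 65),
                       net_cfg = network_config(input_size = 32), fold_seed = 66)
  expect_identical(sum(vapply(cv$fold_results, function(f) length(f$val_idx),
                              integer(1))),
                   length(fs$labels))
  expect_true(all(cv$oof_pred %in% 1:5))
  expect_identical(cv$report$pooled$n, length(fs$labels))
  expect_identical(sum(unclass(cv$confusion)), length(fs$labels))
})
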