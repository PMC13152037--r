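# Confusion matrices, one-vs-rest metrics, fold aggregation, noise harness.

test_that("confusion matrix counts truth/prediction pairs", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), n_classes = 2,
                         class_names = c("a", "b"))
  expect_identical(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
                                       dimnames = list(true = c("a", "b"),
                                                       predicted = c("a", "b"))))
  perfect <- confusion_matrix(rep(1:5, 4), rep(1:5, 4))
  expect_identical(sum(diag(unclass(perfect))), 20L)
  expect_identical(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)
  expect_error(confusion_matrix(c(1, 6), c(1, 1)), "outside")
})

test_that("matrix totals are conserved for random labelings", {
  set.seed(71)
  for (r in 1:100) {
    n <- sample(5:60, 1)
    yt <- sample(1:5, n, replace = TRUE)
    yp <- sample(1:5, n, replace = TRUE)
    expect_identical(sum(unclass(confusion_matrix(yt, yp))), n)
  }
})

test_that("class names are accepted as labels", {
  cm <- confusion_matrix(c("copd", "healthy"), c("copd", "copd"))
  expect_identical(unname(unclass(cm)["copd", "copd"]), 1L)
})

test_that("a diagonal confusion matrix scores 100% everywhere", {
  cm <- confusion_matrix(rep(1:5, each = 3), rep(1:5, each = 3))
  rep_ <- metrics_from_confusion(cm)
  expect_equal(rep_$accuracy, 100)
  expect_true(all(rep_$per_class$precision == 100))
  expect_true(all(rep_$per_class$recall == 100))
  expect_true(all(rep_$per_class$f1 == 100))
  expect_true(all(rep_$per_class$specificity == 100))
})

test_that("metrics match hand-computed values on the TP8/FN2/FP1/TN9 case", {
  cm <- matrix(c(8L, 1L, 2L, 9L), 2, 2,
               dimnames = list(true = c("pos", "neg"),
                               predicted = c("pos", "neg")))
  # rows true, cols predicted: TP=8, FN=2, FP=1, TN=9 for class "pos"
  rep_ <- metrics_from_confusion(cm)
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(pos$precision, 100 * 8 / 9, tolerance = 1e-9)   # 88.89%
  expect_equal(pos$recall, 80)
  expect_equal(pos$f1, 100 * 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-9)                               # 84.21%
  expect_equal(pos$specificity, 90)
  expect_equal(rep_$accuracy, 85)
})

test_that("accuracy equals mean per-sample correctness on random labelings", {
  set.seed(72)
  for (r in 1:100) {
    n <- sample(10:80, 1)
    yt <- sample(1:5, n, replace = TRUE)
    yp <- sample(1:5, n, replace = TRUE)
    rep_ <- metrics_from_confusion(confusion_matrix(yt, yp))
    expect_equal(rep_$accuracy, 100 * mean(yt == yp), tolerance = 1e-12)
  }
})

test_that("one-vs-rest accounting and macro averages are self-consistent", {
  set.seed(73)
  yt <- sample(1:5, 200, replace = TRUE)
  yp <- sample(1:5, 200, replace = TRUE)
  cm <- unclass(confusion_matrix(yt, yp))
  rep_ <- metrics_from_confusion(cm)
  for (c in 1:5) {
    tp <- cm[c, c]
    expect_identical(tp + (sum(cm[c, ]) - tp), sum(cm[c, ]))   # TP+FN = row
    expect_identical(tp + (sum(cm[, c]) - tp), sum(cm[, c]))   # TP+FP = col
  }
  expect_equal(unname(rep_$macro["f1"]), mean(rep_$per_class$f1),
               tolerance = 1e-9)
  # permutation invariance in sample order
  perm <- sample(200)
  rep2 <- metrics_from_confusion(confusion_matrix(yt[perm], yp[perm]))
  expect_equal(rep2$per_class, rep_$per_class)
})

test_that("undefined 0/0 ratios are reported as 0 and flagged", {
  cm <- matrix(c(5L, 0L, 0L, 0L), 2, 2)   # class 2 never occurs nor predicted
  rep_ <- metrics_from_confusion(cm)
  expect_equal(rep_$per_class$precision[2], 0)
  expect_true(rep_$undefined[2, "precision"])
  expect_error(metrics_from_confusion(matrix(0L, 2, 2)), "empty")
})

test_that("fold aggregation reproduces the closed-form mean/SD/CI", {
  same <- aggregate_folds(rep(84, 5))
  expect_equal(same$sd, 0)
  expect_equal(same$ci, c(84, 84))

  a <- aggregate_folds(c(80, 82, 84, 86, 88))
  expect_equal(a$mean, 84)
  expect_equal(a$sd, sqrt(10))
  se <- sqrt(10) / sqrt(5)
  expect_equal(a$ci, c(84 - stats::qnorm(0.975) * se, 84 + stats::qnorm(0.975) * se))
  expect_equal(a$ci, c(81.23, 86.77), tolerance = 1e-3)
  expect_equal(a$ci_t, 84 + c(-1, 1) * stats::qt(0.975, 4) * se)
  expect_error(aggregate_folds(84), "at least 2")
})

test_that("CI width grows with the spread at fixed fold count", {
  set.seed(74)
  widths <- vapply(seq(0.5, 5, length.out = 10), function(s) {
    v <- 84 + s * scale(rnorm(5))[, 1]
    a <- aggregate_folds(v)
    a$ci[2] - a$ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) >= -1e-9))
})

test_that("additive noise hits the requested SNR and is seed-deterministic", {
  set.seed(75)
  s <- segment(rnorm(48000), 16000)
  for (snr in c(30, 20, 10)) {
    noisy <- add_noise_at_snr(s, snr, seed = 76)
    realized <- attr(noisy, "realized_snr_db")
    # recompute independently from the difference signal
    pn <- mean((noisy$samples - s$samples)^2)
    expect_equal(realized, 10 * log10(mean(s$samples^2) / pn), tolerance = 1e-9)
    expect_lt(abs(realized - snr), 0.5)
  }
  a <- add_noise_at_snr(s, 20, seed = 77)
  b <- add_noise_at_snr(s, 20, seed = 77)
  expect_identical(a$samples, b$samples)
  # vanishing-noise limit
  quiet <- add_noise_at_snr(s, 100, seed = 78)
  rel <- sqrt(mean((quiet$samples - s$samples)^2) / mean(s$samples^2))
  expect_lt(rel, 1e-4)
  expect_error(add_noise_at_snr(segment(numeric(10), 16000), 20), "zero power")
})

test_that("the robustness table starts from the exact noiseless evaluation", {
  st <- small_trained()
  fs <- small_feature_set()
  segs <- fs$segments[st$va[1:20]]
  tab <- noise_robustness_eval(st$model, segs, snr_db = c(30, 10), seed = 79,
                               input_size = 32)
  expect_identical(nrow(tab), 3L)
  expect_true(is.na(tab$snr_db[1]))
  # the noiseless row must equal a direct evaluation exactly
  fz <- featurize_segments(segs, size = 32)
  pred <- predict_classes(st$model, fz$inputs)
  plain <- metrics_from_confusion(confusion_matrix(fz$labels, pred$class))
  expect_identical(tab$accuracy[1], plain$accuracy)
  expect_identical(tab$f1[1], unname(plain$macro["f1"]))
})
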