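# Metrics: confusion matrix, one-vs-rest precision/recall/F1/specificity,
# fold aggregation with SD and 95% CI, and the additive-noise robustness
# protocol.

#' Confusion matrix of true vs predicted classes
#'
#' @param y_true,y_pred Equal-length label vectors: 1-based integer indices
#'   or class-name strings.
#' @param n_classes Number of classes (default 5).
#' @param class_names Row/column names (default [cough_classes()]).
#' @return A `confusion_matrix`: n x n integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 5,
                             class_names = NULL) {
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  if (is.null(class_names))
    class_names <- if (n_classes == length(COUGH_CLASSES)) COUGH_CLASSES
                   else paste0("class", seq_len(n_classes))
  to_idx <- function(y) {
    if (is.character(y) || is.factor(y)) y <- match(as.character(y), class_names)
    as.integer(y)
  }
  yt <- to_idx(y_true); yp <- to_idx(y_pred)
  if (anyNA(yt) || anyNA(yp) || any(yt < 1 | yt > n_classes) ||
      any(yp < 1 | yp > n_classes))
    stopf("labels outside 1..%d (or unknown class names)", n_classes)
  cm <- matrix(0L, n_classes, n_classes, dimnames = list(true = class_names,
                                                         predicted = class_names))
  for (i in seq_along(yt)) cm[yt[i], yp[i]] <- cm[yt[i], yp[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Point metrics from a confusion matrix
#'
#' One-vs-rest accounting per class c: TP = cm[c,c], FN = row c - TP,
#' FP = column c - TP, TN = remainder. Precision = TP/(TP+FP), recall
#' (sensitivity) = TP/(TP+FN), specificity = TN/(TN+FP), F1 = harmonic mean
#' of precision and recall, accuracy = trace/total. All reported in percent.
#' Undefined 0/0 ratios are reported as 0 and flagged.
#'
#' @param cm A [confusion_matrix()] (any square count matrix works).
#' @return A `metrics_report`: list with `per_class` data.frame (precision,
#'   recall, f1, specificity, support), `accuracy`, `macro` (named vector of
#'   macro averages), `undefined` (logical flag matrix), `n`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stopf("empty evaluation: confusion matrix is all zero")
  k <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  undefined <- cbind(precision = tp + fp == 0, recall = tp + fn == 0,
                     f1 = precision + recall == 0, specificity = tn + fp == 0)
  per_class <- data.frame(class = rownames(cm) %||% paste0("class", seq_len(k)),
                          precision = 100 * precision, recall = 100 * recall,
                          f1 = 100 * f1, specificity = 100 * specificity,
                          support = rowSums(cm), row.names = NULL)
  structure(list(per_class = per_class,
                 accuracy = 100 * sum(tp) / total,
                 macro = c(precision = mean(per_class$precision),
                           recall = mean(per_class$recall),
                           f1 = mean(per_class$f1),
                           specificity = mean(per_class$specificity)),
                 undefined = undefined, n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics: n = %d, accuracy %.2f%%, macro F1 %.2f%%>\n",
              x$n, x$accuracy, x$macro["f1"]))
  print(format(x$per_class, digits = 4))
  invisible(x)
}

#' Aggregate a metric across cross-validation folds
#'
#' Mean, sample standard deviation (n-1 denominator) and a 95% confidence
#' interval mean +/- 1.96 * SD / sqrt(k) (normal approximation); a
#' Student-t interval (k-1 df) is reported alongside.
#'
#' @param values Numeric vector of per-fold metric values (length >= 2).
#' @param confidence Confidence level (default 0.95).
#' @return List with `mean`, `sd`, `ci` (normal c(lower, upper)),
#'   `ci_t` (Student-t), `k`.
#' @export
aggregate_folds <- function(values, confidence = 0.95) {
  k <- length(values)
  if (k < 2) stopf("need at least 2 fold values to aggregate, got %d", k)
  m <- mean(values)
  s <- sd(values)
  zq <- stats::qnorm(1 - (1 - confidence) / 2)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = k - 1)
  se <- s / sqrt(k)
  list(mean = m, sd = s, ci = c(m - zq * se, m + zq * se),
       ci_t = c(m - tq * se, m + tq * se), k = k)
}

# Aggregate per-fold metrics reports into one summary table.
aggregate_fold_reports <- function(fold_reports, pooled_cm) {
  k <- length(fold_reports)
  agg_one <- function(get) aggregate_folds(vapply(fold_reports, get, numeric(1)))
  rows <- list()
  for (metric in c("precision", "recall", "f1", "specificity")) {
    for (cl in fold_reports[[1]]$per_class$class) {
      a <- agg_one(function(r) r$per_class[r$per_class$class == cl, metric])
      rows[[length(rows) + 1]] <- data.frame(metric = metric, class = cl,
                                             mean = a$mean, sd = a$sd,
                                             ci_lower = a$ci[1], ci_upper = a$ci[2])
    }
    a <- agg_one(function(r) unname(r$macro[metric]))
    rows[[length(rows) + 1]] <- data.frame(metric = metric, class = "macro",
                                           mean = a$mean, sd = a$sd,
                                           ci_lower = a$ci[1], ci_upper = a$ci[2])
  }
  a <- agg_one(function(r) r$accuracy)
  rows[[length(rows) + 1]] <- data.frame(metric = "accuracy", class = "overall",
                                         mean = a$mean, sd = a$sd,
                                         ci_lower = a$ci[1], ci_upper = a$ci[2])
  list(summary = do.call(rbind, rows), pooled = metrics_from_confusion(pooled_cm),
       k = k)
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' Noise power is scaled so 10*log10(P_signal / P_noise) equals `snr_db` in
#' expectation; at 3 s x 16 kHz the realized SNR is within about 0.1 dB.
#'
#' @param s A [segment()] (or [waveform()]) with nonzero power.
#' @param snr_db Target SNR in decibels.
#' @param seed RNG seed; the same seed reproduces the same noise.
#' @return Object of the same class with noise added; the realized SNR is
#'   stored in attribute "realized_snr_db".
#' @export
add_noise_at_snr <- function(s, snr_db, seed = 1) {
  x <- s$samples
  p_sig <- mean(x^2)
  if (p_sig == 0) stopf("SNR undefined: segment has zero power")
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- with_local_seed(seed, rnorm(length(x), 0, sigma))
  s$samples <- x + noise
  attr(s, "realized_snr_db") <- 10 * log10(p_sig / mean(noise^2))
  s
}

#' Noise-robustness evaluation of a trained model
#'
#' For each SNR the test *waveforms* are corrupted with white Gaussian
#' noise, re-featurized and re-evaluated; a noiseless first row reproduces
#' the plain evaluation. Mirrors the protocol of degrading only the test
#' audio.
#'
#' @param model A trained `cam_resnet` model.
#' @param segments List of labelled [segment()]s (the evaluation split).
#' @param snr_db Numeric vector of SNRs in dB (default c(30, 20, 10)).
#' @param seed Master seed for the noise realizations.
#' @param input_size Model input size in pixels.
#' @param ... Passed to [spectrogram_image()] via [featurize_segments()].
#' @return data.frame with one row per condition: snr_db (NA = noiseless),
#'   precision, recall, f1, specificity (macro, %), accuracy (%).
#' @export
noise_robustness_eval <- function(model, segments, snr_db = c(30, 20, 10),
                                  seed = 1, input_size = NULL, ...) {
  if (!length(segments)) stopf("empty test set")
  if (is.null(input_size)) input_size <- model$cfg$input_size
  eval_once <- function(segs) {
    fz <- featurize_segments(segs, size = input_size, ...)
    if (anyNA(fz$labels)) stopf("noise evaluation needs labelled segments")
    pred <- predict_classes(model, fz$inputs)
    metrics_from_confusion(
      confusion_matrix(fz$labels, pred$class, n_classes = model$cfg$num_classes))
  }
  row_of <- function(rep, snr) data.frame(
    snr_db = snr, precision = unname(rep$macro["precision"]),
    recall = unname(rep$macro["recall"]), f1 = unname(rep$macro["f1"]),
    specificity = unname(rep$macro["specificity"]), accuracy = rep$accuracy)
  out <- row_of(eval_once(segments), NA_real_)
  for (j in seq_along(snr_db)) {
    noisy <- lapply(seq_along(segments), function(i)
      add_noise_at_snr(segments[[i]], snr_db[j],
                       seed = stage_seed(seed, sprintf("noise%g_%d", snr_db[j], i))))
    out <- rbind(out, row_of(eval_once(noisy), snr_db[j]))
  }
  out
}
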