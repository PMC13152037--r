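# Stratified k-fold cross-validated training: cross-entropy loss, Adam,
# step-decay learning rate, best-validation checkpointing.

#' Training configuration (defaults follow the study protocol)
#'
#' Cross-entropy loss, Adam (beta1 0.9, beta2 0.999, eps 1e-8), learning
#' rate 0.001 decayed by 0.1 every 7 epochs, 50 epochs, batch size 8, He
#' initialization.
#'
#' @param lr Initial learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param step_size Scheduler step in epochs.
#' @param gamma Learning-rate attenuation coefficient.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, epochs = 50, batch_size = 8,
                         step_size = 7, gamma = 0.1, seed = 1) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 step_size = as.integer(step_size), gamma = gamma,
                 seed = as.integer(seed),
                 optimizer = "adam", loss = "cross_entropy", init = "he"),
            class = "train_config")
}

#' Learning rate at a given epoch under step decay
#'
#' lr(e) = lr0 * gamma^floor(e / step_size) with e counted from 0.
#'
#' @param epoch Epoch index, 0-based.
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  cfg$lr * cfg$gamma^(epoch %/% cfg$step_size)
}

#' Assign samples to cross-validation folds
#'
#' Partitions ids into k near-equal folds (sizes differ by at most one).
#' With `stratified = TRUE` (default) each class is dealt round-robin across
#' folds so per-fold class counts are within one of each other.
#'
#' @param sample_ids Vector of unique sample identifiers.
#' @param labels Class label per sample (required when stratified).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @param stratified Preserve class proportions per fold.
#' @return A `fold_plan`: list with `k`, `assignment` (named integer vector
#'   of fold indices in 1..k, names = sample ids).
#' @export
make_folds <- function(sample_ids, labels = NULL, k = 5, seed = 1,
                       stratified = TRUE) {
  n <- length(sample_ids)
  if (n < k) stopf("cannot split %d samples into %d folds", n, k)
  if (anyDuplicated(sample_ids)) stopf("sample ids must be unique")
  assignment <- integer(n)
  with_local_seed(seed, {
    if (stratified) {
      if (is.null(labels) || length(labels) != n)
        stopf("stratified folds need one label per sample")
      offset <- 0L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        assignment[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
        offset <- (offset + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      assignment[idx] <- (seq_len(n) - 1L) %% k + 1L
    }
  })
  names(assignment) <- as.character(sample_ids)
  structure(list(k = as.integer(k), assignment = assignment), class = "fold_plan")
}

#' Cross-entropy between a true distribution and predicted probabilities
#'
#' H(p, q) = -sum p_i log q_i; for a one-hot p this is -log q(true class).
#' Accepts a one-hot vector or a class index for `p`. Zero predicted
#' probability at the true class is clamped at 1e-12 with a warning.
#'
#' @param p One-hot numeric vector, or a single 1-based class index.
#' @param q Predicted probability vector (entries in [0, 1], sum ~ 1).
#' @return The loss value.
#' @export
cross_entropy_loss <- function(p, q) {
  if (length(p) == 1) {
    idx <- as.integer(p)
  } else {
    if (length(p) != length(q)) stopf("p and q lengths differ")
    idx <- which(p == 1)
    if (length(idx) != 1) stopf("p must be one-hot")
  }
  qi <- q[idx]
  if (qi <= 0) {
    warning("predicted probability at the true class is 0; clamped at 1e-12")
    qi <- 1e-12
  }
  -log(qi)
}

#' Train the network on one train/validation split
#'
#' Runs `cfg$epochs` epochs of Adam on shuffled mini-batches with the
#' step-decay schedule, evaluates validation accuracy after every epoch,
#' and keeps the parameters with the highest validation accuracy (ties go
#' to the earliest epoch).
#'
#' @param train_x H x W x N array of training feature images.
#' @param train_y Integer class labels (1-based), length N.
#' @param val_x,val_y Validation split in the same form.
#' @param cfg A [train_config()].
#' @param net_cfg A [network_config()].
#' @param model Optional pre-built model (overrides `net_cfg`/seed init).
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpointed weights), `history`
#'   (data.frame epoch, lr, train_loss, val_acc), `best_epoch`,
#'   `best_val_acc`.
#' @export
train_model <- function(train_x, train_y, val_x, val_y,
                        cfg = train_config(), net_cfg = network_config(),
                        model = NULL, verbose = FALSE) {
  n_classes <- if (is.null(model)) net_cfg$num_classes else model$cfg$num_classes
  if (length(unique(train_y)) < n_classes)
    stopf("training split is missing %d of %d classes",
          n_classes - length(unique(train_y)), n_classes)
  if (dim(train_x)[3] != length(train_y)) stopf("train_x / train_y size mismatch")
  if (is.null(model)) model <- build_cam_resnet18(net_cfg, seed = cfg$seed)
  opt <- adam_init(model$params)
  n <- length(train_y)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL, running = NULL)

  with_local_seed(cfg$seed + 77, for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, cfg)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- train_x[, , idx, drop = FALSE]
      fw <- model_forward(model, xb, training = TRUE)
      model$running <- fw$running
      le <- softmax_xent(fw$logits, train_y[idx])
      if (!is.finite(le$loss))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      grads <- model_backward(model, fw$cache, le$grad)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
      losses <- c(losses, le$loss)
    }
    pred <- predict_classes(model, val_x, batch_size = max(cfg$batch_size, 16))
    acc <- mean(pred$class == val_y)
    history[nrow(history) + 1, ] <- list(epoch, lr, mean(losses), acc)
    if (acc > best$acc) {
      best <- list(acc = acc, epoch = epoch, params = model$params,
                   running = model$running)
    }
    if (verbose)
      message(sprintf("epoch %2d  lr %.2g  loss %.4f  val acc %.3f",
                      epoch, lr, mean(losses), acc))
  })
  model$params <- best$params
  model$running <- best$running
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_acc = best$acc)
}

#' Run k-fold cross-validated training
#'
#' Trains one model per fold (fold f is the validation split), collects
#' per-fold metrics, and returns out-of-fold predictions covering every
#' sample exactly once.
#'
#' @param inputs H x W x N array of feature images.
#' @param labels Integer class labels (1-based), length N.
#' @param k Number of folds.
#' @param cfg A [train_config()]; fold f trains with seed `cfg$seed + f`.
#' @param net_cfg A [network_config()].
#' @param fold_seed Seed for the fold assignment.
#' @param verbose Print progress.
#' @return List with `fold_plan`, `fold_results` (per fold: history,
#'   best_val_acc, metrics report, model), `oof_pred` (out-of-fold predicted
#'   classes), `confusion` (pooled confusion matrix), `report` (aggregated
#'   metrics with per-fold SD and CI).
#' @export
crossval_train <- function(inputs, labels, k = 5, cfg = train_config(),
                           net_cfg = network_config(), fold_seed = 1,
                           verbose = FALSE) {
  n <- length(labels)
  plan <- make_folds(seq_len(n), labels, k = k, seed = fold_seed)
  oof <- integer(n)
  fold_results <- list()
  per_fold_metrics <- list()
  for (f in seq_len(k)) {
    tr <- which(plan$assignment != f)
    va <- which(plan$assignment == f)
    fcfg <- cfg
    fcfg$seed <- cfg$seed + f
    res <- train_model(inputs[, , tr, drop = FALSE], labels[tr],
                       inputs[, , va, drop = FALSE], labels[va],
                       cfg = fcfg, net_cfg = net_cfg, verbose = verbose)
    pred <- predict_classes(res$model, inputs[, , va, drop = FALSE])
    oof[va] <- pred$class
    cm <- confusion_matrix(labels[va], pred$class, n_classes = net_cfg$num_classes)
    rep_f <- metrics_from_confusion(cm)
    per_fold_metrics[[f]] <- rep_f
    fold_results[[f]] <- list(history = res$history, best_epoch = res$best_epoch,
                              best_val_acc = res$best_val_acc, metrics = rep_f,
                              model = res$model, val_idx = va)
    if (verbose) message(sprintf("fold %d/%d: val acc %.3f", f, k, res$best_val_acc))
  }
  cm_all <- confusion_matrix(labels, oof, n_classes = net_cfg$num_classes)
  list(fold_plan = plan, fold_results = fold_results, oof_pred = oof,
       confusion = cm_all,
       report = aggregate_fold_reports(per_fold_metrics, cm_all))
}
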