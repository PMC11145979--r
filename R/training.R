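# Training and evaluation harness: AdamW + cross-entropy with multiplicative
# step learning-rate decay, confusion-matrix metrics, one-vs-rest macro AUC,
# and stratified k-fold cross-validation. CPU-only and deterministic under a
# fixed seed.

#' Training configuration
#'
#' Defaults follow the published training recipe (AdamW, cross-entropy,
#' batch 112, 120 epochs, initial learning rate 0.005 halved on a fixed
#' cadence). The decay cadence itself is a design choice (every 30 epochs);
#' the recipe names only the 0.5 factor.
#'
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor in (0, 1].
#' @param decay_every epochs between decay events.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param weight_decay AdamW decoupled weight decay.
#' @param beta1,beta2,eps AdamW moment parameters.
#' @param seed integer seed controlling shuffling, dropout and weight
#'   initialisation performed inside [ppw_train()].
#' @param device only `"cpu"` is supported.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 0.005, lr_decay = 0.5, decay_every = 30L,
                         batch_size = 112L, epochs = 120L,
                         weight_decay = 0.01, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L, device = "cpu") {
  if (batch_size < 1) abort("`batch_size` must be at least 1")
  if (lr <= 0) abort("`lr` must be positive")
  if (lr_decay <= 0 || lr_decay > 1) abort("`lr_decay` must lie in (0, 1]")
  if (device != "cpu") abort("only device = 'cpu' is supported")
  structure(list(lr = lr, lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed), device = device),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A small-problem profile for CPU smoke experiments (32 px inputs, small
#' batches, few epochs), distinct from the full published recipe in
#' [train_config()].
#'
#' @param epochs,batch_size,lr,seed overrides.
#' @return a [train_config()].
#' @export
desk_train_config <- function(epochs = 6L, batch_size = 32L, lr = 1e-3,
                              seed = 1L) {
  train_config(lr = lr, lr_decay = 0.5, decay_every = 4L,
               batch_size = batch_size, epochs = epochs,
               weight_decay = 1e-4, seed = seed)
}

#' Learning rate at a given epoch under step decay
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch index.
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^((epoch - 1) %/% cfg$decay_every)
}

# forward through all layers keeping caches; returns scores, caches, model
forward_train <- function(model, x, training = TRUE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    model$layers[[i]] <- r$layer
  }
  list(scores = x, caches = caches, model = model)
}

backward_train <- function(model, caches, dscores) {
  grads <- vector("list", length(model$layers))
  dy <- dscores
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # plain [[<-]] would drop NULL entries
  }
  grads
}

adamw_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (is.null(ly$params)) return(NULL)
    lapply(ly$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adamw_step <- function(model, grads, state, t, lr, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g[[nm]]
      st$v <- b2 * st$v + (1 - b2) * g[[nm]]^2
      p <- model$layers[[i]]$params[[nm]]
      upd <- (st$m / c1) / (sqrt(st$v / c2) + cfg$eps)
      model$layers[[i]]$params[[nm]] <- p - lr * (upd + cfg$weight_decay * p)
      state[[i]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}

#' Recalibrate batch-norm running statistics
#'
#' After short training runs the exponentially-averaged running statistics
#' lag the (still moving) parameters, so evaluation-mode normalisation can be
#' far off the batch statistics the network was actually trained with. This
#' pass freezes the weights and replaces every running mean/variance with the
#' cumulative average of batch statistics over `x`.
#'
#' @param model a materialised `ppw_model`.
#' @param x images (n, 3, size, size), typically the training set.
#' @param batch_size statistics batch size.
#' @return the model with refreshed batch-norm buffers.
#' @export
refresh_bn <- function(model, x, batch_size = 64L) {
  bn_idx <- which(vapply(model$layers, function(l) l$type == "bn", logical(1)))
  if (length(bn_idx) == 0) return(model)
  for (i in bn_idx) {
    model$layers[[i]]$buffers$rm[] <- 0
    model$layers[[i]]$buffers$rv[] <- 0
  }
  n <- dim(x)[1]
  b <- 0L
  for (b0 in seq(1L, n, by = batch_size)) {
    b <- b + 1L
    for (i in bn_idx) model$layers[[i]]$momentum <- 1 / b
    bi <- b0:min(b0 + batch_size - 1L, n)
    model <- forward_train(model, x[bi, , , , drop = FALSE], training = TRUE)$model
  }
  for (i in bn_idx) model$layers[[i]]$momentum <- NULL
  model
}

check_train_inputs <- function(x, y) {
  stopifnot_4d(x)
  if (length(y) != dim(x)[1]) abort("length(y) must match the batch dimension of x")
  if (length(y) == 0) abort("dataset is empty")
  if (length(unique(y)) < 2) abort("training needs at least 2 classes")
}

#' Train a model
#'
#' Minibatch AdamW on softmax cross-entropy with multiplicative step decay
#' of the learning rate. All randomness (shuffling, dropout) flows from
#' `cfg$seed`. When validation data is supplied the returned model is the
#' epoch checkpoint with the best validation accuracy; otherwise the final
#' epoch is returned.
#'
#' @param model a materialised `ppw_model`.
#' @param x training images, array (n, 3, size, size).
#' @param y integer labels in 1..num_classes.
#' @param cfg a [train_config()].
#' @param x_val,y_val optional validation set.
#' @param steps optional cap on total update steps (for short smoke fits).
#' @param verbose print one line per epoch.
#' @return an object of class `ppw_fit`: `model`, `log` (tibble with epoch,
#'   lr, loss, acc, val_acc), `config`.
#' @export
ppw_train <- function(model, x, y, cfg = train_config(), x_val = NULL,
                      y_val = NULL, steps = Inf, verbose = FALSE) {
  check_train_inputs(x, y)
  if (max(y) > model$config$num_classes) {
    abort("labels exceed the model's class count")
  }
  n <- dim(x)[1]
  state <- adamw_init(model)
  t <- 0L
  best <- list(metric = -Inf, model = model)
  log <- list()
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      if (t >= steps) break
      lr <- lr_at_epoch(cfg, epoch)
      idx <- sample.int(n)
      losses <- c(); correct <- 0L; seen <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        if (t >= steps) break
        bi <- idx[b0:min(b0 + cfg$batch_size - 1L, n)]
        xb <- x[bi, , , , drop = FALSE]
        yb <- y[bi]
        fw <- forward_train(model, xb, training = TRUE)
        model <- fw$model
        ls <- softmax_ce(fw$scores, yb)
        if (!is.finite(ls$loss)) abort("training loss became non-finite")
        grads <- backward_train(model, fw$caches, ls$dscores)
        t <- t + 1L
        st <- adamw_step(model, grads, state, t, lr, cfg)
        model <- st$model; state <- st$state
        losses <- c(losses, ls$loss)
        correct <- correct + sum(max.col(ls$probs, ties.method = "first") == yb)
        seen <- seen + length(yb)
      }
      val_acc <- NA_real_
      if (!is.null(x_val)) {
        val_acc <- mean(predict_batched(model, x_val) == y_val)
      }
      metric <- if (is.na(val_acc)) correct / seen else val_acc
      if (metric >= best$metric) best <- list(metric = metric, model = model)
      log[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                     loss = mean(losses),
                                     acc = correct / seen, val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d lr %.5f loss %.4f acc %.3f val %.3f",
                        epoch, lr, mean(losses), correct / seen, val_acc))
      }
    }
  })
  best$model <- refresh_bn(best$model, x, cfg$batch_size)
  structure(list(model = best$model, final_model = model,
                 log = dplyr::bind_rows(log), config = cfg),
            class = "ppw_fit")
}

# memory-bounded prediction
predict_batched <- function(model, x, chunk = 64L, type = "class") {
  n <- dim(x)[1]
  out <- vector("list", ceiling(n / chunk))
  j <- 0L
  for (b0 in seq(1L, n, by = chunk)) {
    j <- j + 1L
    bi <- b0:min(b0 + chunk - 1L, n)
    out[[j]] <- predict(model, x[bi, , , , drop = FALSE], type = type)
  }
  if (type == "class") unlist(out) else do.call(rbind, out)
}

#' Confusion matrix from labels and predictions
#'
#' @param truth,pred integer vectors in 1..n_classes (rows = truth,
#'   columns = predicted).
#' @param n_classes number of classes.
#' @return integer K x K matrix of class `ppw_confusion`.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(truth, pred)) {
  stopifnot(length(truth) == length(pred))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  structure(cm, class = c("ppw_confusion", "matrix", "array"))
}

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest reduction per class: accuracy `(TP+TN)/(TP+FP+TN+FN)`,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and F1 `2PR/(P+R)` (defined
#' as 0 when `P + R = 0`). Overall accuracy is the trace over the total.
#'
#' @param cm a square count matrix (rows = truth).
#' @return list with `overall_accuracy`, `per_class` tibble and `macro`
#'   one-row tibble (macro precision/recall/F1 and mean per-class accuracy).
#' @export
metrics_from_cm <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) abort("confusion matrix is empty")
  k <- nrow(cm)
  per <- purrr::map_dfr(seq_len(k), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    tn <- total - tp - fp - fn
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble::tibble(class = c, tp = tp, fp = fp, tn = tn, fn = fn,
                   accuracy = (tp + tn) / total, precision = p, recall = r,
                   f1 = f1)
  })
  list(
    overall_accuracy = sum(diag(cm)) / total,
    per_class = per,
    macro = tibble::tibble(
      accuracy = mean(per$accuracy),
      precision = mean(per$precision),
      recall = mean(per$recall),
      f1 = mean(per$f1))
  )
}

#' One-vs-rest macro AUC from class scores
#'
#' @param truth integer labels in 1..K.
#' @param probs matrix (n, K) of class scores or probabilities.
#' @return macro-averaged AUC; classes absent from `truth` are skipped.
#' @export
macro_auc <- function(truth, probs) {
  k <- ncol(probs)
  aucs <- c()
  for (c in seq_len(k)) {
    resp <- as.integer(truth == c)
    if (length(unique(resp)) < 2) next
    roc <- pROC::roc(resp, probs[, c], quiet = TRUE, direction = "<")
    aucs <- c(aucs, as.numeric(pROC::auc(roc)))
  }
  mean(aucs)
}

#' Evaluate a model on labelled data
#'
#' @param model a `ppw_model` or `ppw_fit`.
#' @param x images (n, 3, size, size).
#' @param y integer labels.
#' @return an object of class `ppw_eval`: confusion matrix, overall accuracy,
#'   per-class and macro metrics, macro AUC.
#' @export
ppw_evaluate <- function(model, x, y) {
  if (inherits(model, "ppw_fit")) model <- model$model
  check_train_inputs(x, y)
  if (max(y) > model$config$num_classes) {
    abort("labels contain a class absent from the model head")
  }
  probs <- predict_batched(model, x, type = "prob")
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(y, pred, model$config$num_classes)
  m <- metrics_from_cm(cm)
  structure(list(confusion = cm, overall_accuracy = m$overall_accuracy,
                 per_class = m$per_class, macro = m$macro,
                 auc = macro_auc(y, probs), n = length(y)),
            class = "ppw_eval")
}

#' @export
print.ppw_eval <- function(x, ...) {
  cat(sprintf("<ppw_eval> n = %d  ACC = %.4f  macro P/R/F1 = %.4f/%.4f/%.4f  AUC = %.4f\n",
              x$n, x$overall_accuracy, x$macro$precision, x$macro$recall,
              x$macro$f1, x$auc))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Leave-one-fold-out: each fold serves once as the test set while the
#' remaining folds train a freshly initialised model.
#'
#' @param x images (n, 3, size, size).
#' @param y integer labels.
#' @param model_spec preset name or [arch_config()] used to build each fold's
#'   model.
#' @param k number of folds (>= 2).
#' @param cfg a [train_config()].
#' @param input_size square input side length.
#' @return list with `folds` (per-fold metric tibble) and `summary`
#'   (mean and sd of each metric).
#' @export
crossvalidate <- function(x, y, model_spec = "g_ppw_vgg11", k = 3L,
                          cfg = desk_train_config(), input_size = dim(x)[3]) {
  if (k < 2) abort("`k` must be at least 2")
  check_train_inputs(x, y)
  df <- kfold_split(tibble::tibble(idx = seq_along(y), label = y), k = k,
                    seed = cfg$seed)
  rows <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- df$idx[df$fold != f]
    te <- df$idx[df$fold == f]
    with_local_seed(cfg$seed + f, {
      model <- build_model(model_spec, num_classes = max(y),
                           input_size = input_size)
    })
    fit <- ppw_train(model, x[tr, , , , drop = FALSE], y[tr], cfg)
    ev <- ppw_evaluate(fit, x[te, , , , drop = FALSE], y[te])
    tibble::tibble(fold = f, n_test = length(te),
                   accuracy = ev$overall_accuracy,
                   precision = ev$macro$precision, recall = ev$macro$recall,
                   f1 = ev$macro$f1, auc = ev$auc)
  })
  summary <- tibble::tibble(
    metric = c("accuracy", "precision", "recall", "f1", "auc"),
    mean = vapply(rows[, c("accuracy", "precision", "recall", "f1", "auc")],
                  mean, numeric(1)),
    sd = vapply(rows[, c("accuracy", "precision", "recall", "f1", "auc")],
                stats::sd, numeric(1)))
  list(folds = rows, summary = summary)
}
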