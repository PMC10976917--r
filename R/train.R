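#' Semi-supervised cross-entropy loss
#'
#' Cross-entropy summed over labeled nodes only; unlabeled nodes never
#' contribute (the loss is bit-invariant to their predictions). For two
#' classes with one-hot targets this is exactly the binary form
#' `-sum(Y log p + (1 - Y) log(1 - p))`; more classes use the categorical
#' generalization. Probabilities are clipped to `[1e-12, 1 - 1e-12]` before
#' taking logs.
#'
#' @param probs n x C matrix of row-normalized class probabilities
#' @param labels integer vector of 0-based class indices (NA = unlabeled)
#' @param labeled_mask optional logical vector overriding `!is.na(labels)`
#' @return scalar loss
#' @export
semi_supervised_loss <- function(probs, labels, labeled_mask = NULL) {
  if (is.null(labeled_mask)) labeled_mask <- !is.na(labels)
  idx <- which(labeled_mask)
  if (length(idx) == 0) stop("no labeled nodes in loss")
  p <- pmin(pmax(probs[cbind(idx, labels[idx] + 1L)], 1e-12), 1 - 1e-12)
  -sum(log(p))
}

# Gradient of the masked cross-entropy w.r.t. the logits (softmax shortcut).
loss_grad_logits <- function(probs, labels, labeled_mask = NULL) {
  if (is.null(labeled_mask)) labeled_mask <- !is.na(labels)
  labeled_mask <- labeled_mask & !is.na(labels)
  G <- probs
  lab <- ifelse(is.na(labels), 0L, labels)
  hit <- cbind(seq_len(nrow(G)), lab + 1L)
  G[hit] <- G[hit] - 1
  G[!labeled_mask, ] <- 0
  G
}

## ---- parameter-list arithmetic and Adam -----------------------------------

# Apply f element-wise over the (possibly nested) parameter list structure.
param_map <- function(f, ...) {
  args <- list(...)
  x <- args[[1]]
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i) {
      do.call(param_map, c(list(f), lapply(args, `[[`, i)))
    })
    names(out) <- names(x)
    class(out) <- class(x)
    out
  } else {
    do.call(f, args)
  }
}

param_sq_norm <- function(p) {
  if (is.list(p)) sum(vapply(p, param_sq_norm, numeric(1))) else sum(p^2)
}

adam_init <- function(params) {
  list(m = param_map(function(x) x * 0, params),
       v = param_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (l2 > 0) grads <- param_map(function(g, p) g + l2 * p, grads, params)
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  param_map(function(p, g) p - lr * g, params, grads)
}

## ---- configuration --------------------------------------------------------

#' Base-training configuration
#'
#' Defaults follow the regime of the source experiments: Adam with learning
#' rate 0.001 and L2 weight 0.001, a 150-epoch cap, early stopping on
#' validation macro-F1. The labeled nodes are split 70/15/15 into
#' train/validation/test unless explicit index sets are supplied to
#' [train_dhgnn()].
#'
#' @param lr learning rate
#' @param l2_weight L2 regularization weight (applied through the optimizer)
#' @param max_epochs epoch cap
#' @param dropout dropout rate during training
#' @param patience early-stopping patience (epochs without validation
#'   improvement)
#' @param seed RNG seed covering initialization, the split and dropout
#' @param alpha teleport probability of the directed propagators
#' @param k_max largest proximity order
#' @param heads number of attention heads
#' @param hidden_dim per-head embedding width
#' @param semantic_dim semantic attention width
#' @param split numeric vector of train/validation/test fractions of the
#'   labeled nodes (sums to 1)
#' @export
train_config <- function(lr = 0.001, l2_weight = 0.001, max_epochs = 150,
                         dropout = 0.6, patience = 10, seed = 1,
                         alpha = 0.1, k_max = 2, heads = 8, hidden_dim = 8,
                         semantic_dim = 128, split = c(0.7, 0.15, 0.15)) {
  stopifnot(lr > 0, l2_weight >= 0, dropout >= 0, dropout < 1, patience >= 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-8)
  list(lr = lr, l2_weight = l2_weight, max_epochs = max_epochs,
       dropout = dropout, patience = patience, seed = seed, alpha = alpha,
       k_max = k_max, heads = heads, hidden_dim = hidden_dim,
       semantic_dim = semantic_dim, split = split)
}

#' Read a training configuration from YAML
#'
#' Recognized keys are the arguments of [train_config()] plus an optional
#' `meta:` block with the arguments of [meta_config()]. Unknown keys raise
#' an error. Values omitted from the file keep the documented defaults.
#'
#' @param path YAML file
#' @return list with elements `train` ([train_config()]) and `meta`
#'   ([meta_config()] or NULL when no meta block is present)
#' @export
read_train_config <- function(path) {
  raw <- yaml::read_yaml(path)
  meta_raw <- raw$meta
  raw$meta <- NULL
  known <- names(formals(train_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown training config key(s): ", paste(bad, collapse = ", "))
  tc <- do.call(train_config, raw)
  mc <- NULL
  if (!is.null(meta_raw)) {
    known_m <- names(formals(meta_config))
    bad <- setdiff(names(meta_raw), known_m)
    if (length(bad)) stop("unknown meta config key(s): ", paste(bad, collapse = ", "))
    mc <- do.call(meta_config, meta_raw)
  }
  list(train = tc, meta = mc)
}

#' Split labeled nodes into train/validation/test index sets
#'
#' Stratified by class: each class's labeled nodes are shuffled (seeded)
#' and divided according to the configured fractions, so every class is
#' represented in every split.
#'
#' @param labels 0-based integer labels with NA for unlabeled
#' @param split fractions (train, validation, test), summing to 1
#' @param seed RNG seed
#' @return list of integer index vectors `train`, `val`, `test`
#' @export
split_labeled_nodes <- function(labels, split = c(0.7, 0.15, 0.15), seed = 1) {
  set.seed(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (cl in sort(unique(labels[!is.na(labels)]))) {
    idx <- sample(which(!is.na(labels) & labels == cl))
    n <- length(idx)
    n_tr <- max(1, round(split[1] * n))
    n_va <- max(1, round(split[2] * n))
    n_tr <- min(n_tr, n - 2)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$val <- c(out$val, idx[n_tr + seq_len(min(n_va, n - n_tr - 1))])
    out$test <- c(out$test, idx[(n_tr + min(n_va, n - n_tr - 1) + 1):n])
  }
  lapply(out, sort)
}

## ---- training -------------------------------------------------------------

#' Train the model (base learner)
#'
#' Adam with L2 weight decay on the masked cross-entropy of the training
#' nodes; early stopping monitors validation macro-F1 and restores the
#' best-epoch parameters. Fully deterministic for a fixed seed.
#'
#' @param model a [dhgnn()] model whose graph carries labels
#' @param config a [train_config()]
#' @param init_params optional initial parameters (e.g. from
#'   [meta_train()]); defaults to the model's own initialization
#' @param splits optional list with integer index vectors `train` and `val`
#'   (and optionally `test`); defaults to a stratified split of the labeled
#'   nodes
#' @return list with the trained `model` (best-epoch parameters installed),
#'   `history` data.frame (epoch, train_loss, val_macro_f1), `best_epoch`,
#'   `best_val_f1` and the `splits` used
#' @export
train_dhgnn <- function(model, config = train_config(), init_params = NULL,
                        splits = NULL) {
  set.seed(config$seed)
  labels <- model$graph$labels
  if (is.null(splits)) splits <- split_labeled_nodes(labels, config$split, config$seed)
  if (length(splits$train) == 0 || length(splits$val) == 0) {
    stop("train/validation splits must be non-empty")
  }
  n <- n_nodes(model$graph)
  train_mask <- seq_len(n) %in% splits$train
  params <- init_params %||% model$params
  state <- adam_init(params)
  best <- list(f1 = -Inf, epoch = 0L, params = params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_macro_f1 = numeric())
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    fw <- dhgnn_forward(model, params, training = TRUE)
    loss <- semi_supervised_loss(fw$probs, labels, train_mask)
    if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch)
    dlogits <- loss_grad_logits(fw$probs, labels, train_mask)
    grads <- dhgnn_backward(model, params, fw$cache, dlogits)
    upd <- adam_step(params, grads, state, lr = config$lr, l2 = config$l2_weight)
    params <- upd$params
    state <- upd$state

    probs <- dhgnn_forward(model, params, training = FALSE)$probs
    val_f1 <- macro_f1(probs[splits$val, , drop = FALSE], labels[splits$val])
    history <- rbind(history, data.frame(epoch = epoch, train_loss = loss,
                                         val_macro_f1 = val_f1))
    if (val_f1 > best$f1) {
      best <- list(f1 = val_f1, epoch = epoch, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_f1 = best$f1, splits = splits)
}

## ---- metrics --------------------------------------------------------------

# Macro-F1 from probabilities + true 0-based labels (argmax predictions).
macro_f1 <- function(probs, labels) {
  evaluate_predictions(probs, labels, curves = FALSE)$macro$f1
}

confusion_metrics <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

# Threshold-sweep ROC and PR curves with trapezoidal areas.
score_curves <- function(scores, truth) {
  # truth: logical (positive class); scores: positive-class probability
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  P <- sum(truth)
  N <- sum(!truth)
  tpr <- fpr <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp <- sum(pred & truth)
    fp <- sum(pred & !truth)
    tpr[i] <- if (P > 0) tp / P else NA
    fpr[i] <- if (N > 0) fp / N else NA
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
  }
  auc_trap <- function(x, y) {
    o <- order(x)
    sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
  }
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = thr, recall = tpr, precision = prec),
       roc_auc = auc_trap(fpr, tpr),
       pr_auc = auc_trap(tpr, prec))
}

#' Evaluate predictions
#'
#' Per-class and macro precision, recall and F1 from the confusion counts
#' (`precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`), plus ROC and precision-recall curves computed
#' by a sweep over the unique scores with trapezoidal areas. Binary
#' problems classify by `P(class 1) >= threshold`; multi-class uses argmax
#' (and one-vs-rest curves for class 1 are omitted). With a single-class
#' ground truth the curves are undefined: areas are NA and a warning is
#' raised.
#'
#' @param probs n x C probability matrix
#' @param labels 0-based true labels (no NAs)
#' @param threshold binary decision threshold on the class-1 probability
#' @param curves compute ROC/PR curves (default TRUE)
#' @return object of class `metrics_report`: `per_class` data.frame
#'   (class, tp, fp, fn, tn, precision, recall, f1), `macro` list, and for
#'   binary tasks `roc`, `pr`, `roc_auc`, `pr_auc`
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5, curves = TRUE) {
  stopifnot(!anyNA(labels))
  C <- ncol(probs)
  pred <- if (C == 2) ifelse(probs[, 2] >= threshold, 1L, 0L)
          else max.col(probs) - 1L
  classes <- 0:(C - 1)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    tn <- sum(pred != cl & labels != cl)
    m <- confusion_metrics(tp, fp, fn)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = m["precision"], recall = m["recall"], f1 = m["f1"],
               row.names = NULL)
  }))
  macro <- list(precision = mean(per$precision), recall = mean(per$recall),
                f1 = mean(per$f1))
  rep <- list(per_class = per, macro = macro, threshold = threshold)
  if (curves && C == 2) {
    if (length(unique(labels)) < 2) {
      warning("single-class ground truth: ROC/PR areas undefined")
      rep$roc_auc <- NA_real_
      rep$pr_auc <- NA_real_
    } else {
      cv <- score_curves(probs[, 2], labels == 1)
      rep[c("roc", "pr", "roc_auc", "pr_auc")] <- cv[c("roc", "pr", "roc_auc", "pr_auc")]
    }
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("macro precision/recall/F1:",
      sprintf("%.4f / %.4f / %.4f", x$macro$precision, x$macro$recall, x$macro$f1), "\n")
  if (!is.null(x$roc_auc)) cat("ROC AUC:", sprintf("%.4f", x$roc_auc),
                               " PR AUC:", sprintf("%.4f", x$pr_auc), "\n")
  invisible(x)
}

#' Write a metrics report as JSON (and curves as CSV)
#'
#' @param report a `metrics_report`
#' @param path output JSON path; curves, when present, are written next to
#'   it as `<stem>_roc.csv` and `<stem>_pr.csv`
#' @export
write_metrics <- function(report, path) {
  out <- list(per_class = report$per_class, macro = report$macro,
              threshold = report$threshold,
              roc_auc = report$roc_auc, pr_auc = report$pr_auc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  stem <- sub("\\.json$", "", path)
  if (!is.null(report$roc)) {
    utils::write.csv(report$roc, paste0(stem, "_roc.csv"), row.names = FALSE)
    utils::write.csv(report$pr, paste0(stem, "_pr.csv"), row.names = FALSE)
  }
  invisible(NULL)
}
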