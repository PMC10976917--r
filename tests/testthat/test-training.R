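test_that("masked cross-entropy follows the closed forms", {
  labels <- c(0L, 1L, NA, 0L)
  # perfect one-hot predictions: loss vanishes up to the clip floor
  perfect <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(1, 0))
  expect_lt(semi_supervised_loss(perfect, labels), 3 * 1.2e-11)

  # uniform binary predictions: |y_L| * ln 2
  unif <- matrix(0.5, 4, 2)
  expect_equal(semi_supervised_loss(unif, labels), 3 * log(2))

  # predictions on unlabeled nodes never change the loss (bit-identical)
  set.seed(1)
  p1 <- matrix(runif(8), 4, 2)
  p1 <- p1 / rowSums(p1)
  p2 <- p1
  p2[3, ] <- rev(p2[3, ])
  expect_identical(semi_supervised_loss(p1, labels),
                   semi_supervised_loss(p2, labels))
  expect_error(semi_supervised_loss(p1, rep(NA_integer_, 4)), "no labeled")
})

test_that("confusion-count metrics match direct substitution", {
  # TP=2, FP=1, FN=1: precision = recall = F1 = 2/3
  labels <- c(1L, 1L, 1L, 0L, 0L)
  probs <- cbind(c(0.1, 0.2, 0.9, 0.1, 0.9), c(0.9, 0.8, 0.1, 0.9, 0.1))
  r <- evaluate_predictions(probs, labels, curves = FALSE)
  cls1 <- r$per_class[r$per_class$class == 1, ]
  expect_equal(cls1$tp, 2)
  expect_equal(cls1$fp, 1)
  expect_equal(cls1$fn, 1)
  expect_equal(cls1$precision, 2 / 3)
  expect_equal(cls1$recall, 2 / 3)
  expect_equal(cls1$f1, 2 / 3)

  # TP=1, FP=0, FN=1: precision 1, recall 0.5, F1 = 2/3
  labels2 <- c(1L, 1L, 0L)
  probs2 <- cbind(c(0.1, 0.9, 0.8), c(0.9, 0.1, 0.2))
  c2 <- evaluate_predictions(probs2, labels2, curves = FALSE)$per_class
  expect_equal(c2$precision[2], 1)
  expect_equal(c2$recall[2], 0.5)
  expect_equal(c2$f1[2], 2 / 3)

  # perfect predictions
  perf <- evaluate_predictions(cbind(c(1, 0), c(0, 1)), c(0L, 1L))
  expect_equal(perf$macro$precision, 1)
  expect_equal(perf$macro$recall, 1)
  expect_equal(perf$macro$f1, 1)
})

test_that("F1 identity holds on random confusion tables", {
  set.seed(7)
  for (i in 1:1000) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    m <- metadhgnn:::confusion_metrics(tp, fp, fn)
    p_ref <- if (tp + fp > 0) tp / (tp + fp) else 0
    r_ref <- if (tp + fn > 0) tp / (tp + fn) else 0
    f_ref <- if (p_ref + r_ref > 0) 2 * p_ref * r_ref / (p_ref + r_ref) else 0
    expect_identical(unname(m), c(p_ref, r_ref, f_ref))
    expect_true(all(m >= 0 & m <= 1))
    if (m["precision"] > 0 && m["recall"] > 0) {
      expect_lte(m["f1"], max(m["precision"], m["recall"]) + 1e-12)
      expect_gte(m["f1"], min(m["precision"], m["recall"]) - 1e-12)
    }
  }
})

test_that("curves reach area 1 for separated scores and agree with pROC", {
  labels <- c(rep(0L, 5), rep(1L, 5))
  probs <- cbind(1 - c(1:5 / 10, 6:10 / 10), c(1:5 / 10, 6:10 / 10))
  r <- evaluate_predictions(probs, labels)
  expect_equal(r$roc_auc, 1)
  expect_equal(r$pr_auc, 1)
  expect_true(all(r$roc$fpr >= 0 & r$roc$fpr <= 1))

  set.seed(3)
  sc <- runif(40)
  lb <- as.integer(runif(40) < 0.4)
  r2 <- evaluate_predictions(cbind(1 - sc, sc), lb)
  expect_gte(r2$roc_auc, 0)
  expect_lte(r2$roc_auc, 1)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))
    expect_equal(r2$roc_auc, ref, tolerance = 1e-10)
  }

  expect_warning(r3 <- evaluate_predictions(cbind(1 - sc, sc), rep(1L, 40)),
                 "single-class")
  expect_true(is.na(r3$roc_auc))
})

test_that("stratified splits cover every class and respect fractions", {
  set.seed(5)
  labels <- c(sample(c(0L, 1L), 80, replace = TRUE), rep(NA_integer_, 20))
  sp <- split_labeled_nodes(labels, c(0.7, 0.15, 0.15), seed = 2)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_idx, which(!is.na(labels)))
  for (cl in 0:1) {
    expect_true(any(labels[sp$train] == cl))
    expect_true(any(labels[sp$val] == cl))
    expect_true(any(labels[sp$test] == cl))
  }
  # deterministic for fixed seed
  expect_identical(sp, split_labeled_nodes(labels, c(0.7, 0.15, 0.15), seed = 2))
})

test_that("training respects the epoch cap, restores the best epoch, and is seeded", {
  set.seed(0)
  g <- generate_sbm(sbm_spec(type_counts = c(typeA = 25, typeB = 25),
                             feature_dim = 4, label_fraction = 0.8, seed = 5))
  cfg <- train_config(max_epochs = 12, patience = 12, seed = 3, heads = 2,
                      hidden_dim = 3, semantic_dim = 8, dropout = 0.3)
  mcfg <- dhgnn_config(hidden_dim = 3, heads = 2, semantic_dim = 8,
                       k_max = 2, dropout = 0.3)
  model <- dhgnn(g, sbm_default_metapaths(), config = mcfg, seed = 3)
  tr <- train_dhgnn(model, cfg)
  expect_lte(nrow(tr$history), 12)
  expect_equal(tr$best_val_f1, max(tr$history$val_macro_f1))
  expect_equal(tr$history$val_macro_f1[tr$best_epoch], tr$best_val_f1)

  # fixed seed reruns bit-identically
  tr2 <- train_dhgnn(model, cfg)
  expect_identical(tr$model$params, tr2$model$params)
  expect_identical(tr$history, tr2$history)

  # externally supplied initial parameters load and train
  tr3 <- train_dhgnn(model, cfg, init_params = tr$model$params)
  expect_s3_class(tr3$model, "dhgnn")
})

test_that("training config YAML round-trips with defaults and rejects unknown keys", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("lr: 0.005", "max_epochs: 99",
               "meta:", "  k_shot: 4", "  episodes: 7"), y)
  cfg <- read_train_config(y)
  expect_equal(cfg$train$lr, 0.005)
  expect_equal(cfg$train$max_epochs, 99)
  expect_equal(cfg$train$l2_weight, 0.001)  # default preserved
  expect_equal(cfg$meta$k_shot, 4)
  expect_equal(cfg$meta$episodes, 7)

  writeLines("not_a_key: 1", y)
  expect_error(read_train_config(y), "unknown training config key")
})
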