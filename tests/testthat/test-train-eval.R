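test_that("training runs the requested epochs, reproducibly", {
  g <- make_toy_graph(n = 10, d = 3, p_edge = 0.3, seed = 1)
  cfg <- model_config("gcn", hidden_dim = 4, init_seed = 5)
  tc <- train_config(epochs = 1, lr = 0.01, seed = 2)
  m1 <- train_model(g, cfg, tc)
  expect_length(m1$loss_history, 1L)
  tc5 <- train_config(epochs = 5, lr = 0.01, seed = 2)
  m5a <- train_model(g, cfg, tc5)
  m5b <- train_model(g, cfg, tc5)
  expect_identical(m5a$loss_history, m5b$loss_history)
  expect_identical(m5a$params, m5b$params)
  expect_true(all(is.finite(m5a$loss_history)))
})

test_that("subsample batch mode trains and stays reproducible", {
  g <- make_separable_graph(n_per = 20, seed = 3)
  cfg <- model_config("gcn", hidden_dim = 4, init_seed = 1)
  tc <- train_config(epochs = 30, lr = 0.01, batch_size = 8,
                     batch_mode = "subsample", seed = 9)
  m1 <- train_model(g, cfg, tc)
  m2 <- train_model(g, cfg, tc)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("each architecture learns a separable synthetic graph", {
  g <- make_separable_graph(n_per = 30, seed = 1)
  for (arch in c("gcn", "gat", "gin")) {
    cfg <- model_config(arch, hidden_dim = 8, init_seed = 11)
    tc <- train_config(epochs = 500, lr = 0.01, seed = 4)
    model <- train_model(g, cfg, tc)
    acc <- mean(predict(model, g)$pred == g$labels)
    expect_gte(acc, 0.95)
    # loss should have decreased substantially
    expect_lt(model$loss_history[500], model$loss_history[1])
  }
})

test_that("prediction follows the softmax and the >= 0.5 tie rule", {
  g <- make_toy_graph(n = 6, d = 3, p_edge = 0.4, seed = 2)
  cfg <- model_config("gcn", hidden_dim = 4, init_seed = 3)
  model <- train_model(g, cfg, train_config(epochs = 2, lr = 0.01, seed = 1))
  preds <- predict(model, g)
  logits <- gnn_forward(g, model$params, model$config)
  p2 <- exp(logits[, 2]) / (exp(logits[, 1]) + exp(logits[, 2]))
  expect_lt(max(abs(preds$prob_alnm - p2)), 1e-12)
  expect_identical(preds$pred, as.integer(preds$prob_alnm >= 0.5))
  # explicit tie: equal logits give probability 0.5 and a positive call
  tie_p <- exp(0) / (exp(0) + exp(0))
  expect_identical(as.integer(tie_p >= 0.5), 1L)
})

test_that("tidy and glance summarise models and evaluations", {
  g <- make_separable_graph(n_per = 15, seed = 5)
  model <- train_model(g, model_config("gin", hidden_dim = 4, init_seed = 2),
                       train_config(epochs = 10, lr = 0.01, seed = 3))
  td <- tidy(model)
  expect_identical(names(td), c("epoch", "loss"))
  expect_identical(nrow(td), 10L)
  gl <- glance(model)
  expect_identical(gl$architecture, "gin")
  ev <- evaluate_model(model, g, n_boot = 200, seed = 1)
  expect_s3_class(glance(ev), "tbl_df")
  expect_true(all(c("metric", "value") %in% names(tidy(ev))))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev, "pr"), "ggplot")
  expect_s3_class(autoplot(ev, "confusion"), "ggplot")
})

test_that("confusion counting matches a four-way loop and the study's counts", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      y <- rbinom(60, 1, 0.4)
      yh <- rbinom(60, 1, 0.5)
      cm <- confusion_from_predictions(y, yh)
      tp <- fp <- tn <- fn <- 0
      for (i in seq_along(y)) {
        if (y[i] == 1 && yh[i] == 1) tp <- tp + 1
        if (y[i] == 0 && yh[i] == 1) fp <- fp + 1
        if (y[i] == 0 && yh[i] == 0) tn <- tn + 1
        if (y[i] == 1 && yh[i] == 0) fn <- fn + 1
      }
      expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(tp, fp, tn, fn))
    }
  })
  # 28/50 positives and 66/68 negatives correct
  y <- rep(c(1, 0), c(50, 68))
  yh <- c(rep(1, 28), rep(0, 22), rep(0, 66), rep(1, 2))
  cm <- confusion_from_predictions(y, yh)
  expect_identical(c(cm$tp, cm$fn, cm$tn, cm$fp), c(28L, 22L, 66L, 2L))
  cm5 <- confusion_from_predictions(rep(1, 5), rep(1, 5))
  expect_identical(c(cm5$tp, cm5$fp, cm5$tn, cm5$fn), c(5L, 0L, 0L, 0L))
})

test_that("metrics handle perfection and undefined denominators", {
  perfect <- classification_metrics(confusion_matrix(7, 0, 9, 0))
  expect_equal(unlist(perfect[, c("sen", "spec", "ppv", "npv", "acc", "f1")]),
               c(sen = 1, spec = 1, ppv = 1, npv = 1, acc = 1, f1 = 1))
  nopred <- classification_metrics(confusion_matrix(0, 0, 10, 5))
  expect_true(is.na(nopred$ppv))
  expect_equal(nopred$spec, 1)
})

test_that("accuracy is the prevalence-weighted mean of sen and spec", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      cts <- rmultinom(1, 200, c(0.3, 0.2, 0.35, 0.15))[, 1] + 1
      m <- classification_metrics(
        confusion_matrix(cts[1], cts[2], cts[3], cts[4]))
      prev <- (m$tp + m$fn) / (m$tp + m$fp + m$tn + m$fn)
      expect_equal(m$acc, prev * m$sen + (1 - prev) * m$spec,
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the Mann-Whitney statistic, including under ties", {
  withr::with_seed(9, {
    y <- rbinom(200, 1, 0.4)
    scores <- round(runif(200), 2)  # rounding forces ties
  })
  r <- roc_auc(scores, y)
  expect_lt(abs(r$auc - oracle_mw_auc(scores, y)), 1e-12)
  # degenerate cases
  expect_equal(roc_auc(y, y)$auc, 1)
  expect_equal(roc_auc(rep(0.3, length(y)), y)$auc, 0.5)
  # ROC points monotone in FPR
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(10, {
    y <- rbinom(150, 1, 0.5)
    s <- rnorm(150)
  })
  base <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(plogis(3 * s + 1), y)$auc, base, tolerance = 1e-12)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    y <- rbinom(120, 1, 0.4)
    s <- runif(120)
  })
  ref <- as.numeric(suppressMessages(pROC::auc(
    pROC::roc(y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("bootstrap AUC intervals behave as intervals should", {
  # perfect separation pins the interval at [1, 1]
  y <- rep(c(0, 1), each = 20)
  s <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  ci <- auc_ci(s, y, n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  # the interval contains the point AUC for well-behaved data
  contains <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      yy <- rep(c(0, 1), each = 40)
      ss <- rnorm(80, mean = 0.8 * yy)
    })
    point <- roc_auc(ss, yy)$auc
    cc <- auc_ci(ss, yy, n_boot = 200, seed = seed)
    cc$ci_low <= point && point <= cc$ci_high
  }, logical(1))
  expect_true(all(contains))
  # reproducible under seed
  expect_identical(auc_ci(s, y, n_boot = 150, seed = 3),
                   auc_ci(s, y, n_boot = 150, seed = 3))
})

test_that("widening the sample tenfold shrinks the bootstrap interval", {
  widths <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      y_small <- rep(c(0, 1), each = 25)
      s_small <- rnorm(50, 0.6 * y_small)
      y_big <- rep(c(0, 1), each = 250)
      s_big <- rnorm(500, 0.6 * y_big)
    })
    small <- auc_ci(s_small, y_small, n_boot = 300, seed = seed)
    big <- auc_ci(s_big, y_big, n_boot = 300, seed = seed)
    (small$ci_high - small$ci_low) - (big$ci_high - big$ci_low)
  }, numeric(1))
  expect_gt(mean(widths), 0)
})

test_that("precision-recall matches the threshold-enumeration oracle", {
  withr::with_seed(12, {
    y <- rbinom(100, 1, 0.35)
    s <- round(runif(100), 2)
  })
  pr <- pr_curve(s, y)
  expect_lt(abs(pr$avg_precision - oracle_avg_precision(s, y)), 1e-12)
  # perfect scores and uninformative scores
  expect_equal(pr_curve(y, y)$avg_precision, 1)
  expect_equal(pr_curve(rep(0.2, 100), y)$avg_precision, mean(y))
})

test_that("model agreement equals the phi coefficient of the 2x2 table", {
  expect_equal(model_agreement(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
  expect_equal(model_agreement(c(0, 1, 1, 0), c(1, 0, 0, 1)), -1)
  withr::with_seed(13, {
    for (rep in 1:5) {
      a <- rbinom(80, 1, 0.5)
      b <- rbinom(80, 1, 0.5)
      n11 <- sum(a & b); n10 <- sum(a & !b)
      n01 <- sum(!a & b); n00 <- sum(!a & !b)
      phi <- (n11 * n00 - n10 * n01) /
        sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
      expect_lt(abs(model_agreement(a, b) - phi), 1e-12)
    }
  })
  expect_error(model_agreement(c(1, 1), c(0, 1)),
               class = "alngraph_parameter_error")
})

test_that("evaluation reports serialize to flat CSVs", {
  g <- make_separable_graph(n_per = 15, seed = 6)
  model <- train_model(g, model_config("gcn", hidden_dim = 4, init_seed = 4),
                       train_config(epochs = 50, lr = 0.01, seed = 5))
  ev <- evaluate_model(model, g, n_boot = 150, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_eval_report(ev, dir)
  expect_true(all(file.exists(paths)))
  metrics <- readr::read_csv(file.path(dir, "gcn_metrics.csv"),
                             show_col_types = FALSE)
  expect_equal(metrics$acc, ev$metrics$acc)
  expect_equal(metrics$auc, ev$auc)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  g <- make_toy_graph(n = 6, d = 3, p_edge = 0.4, seed = 14)
  g$x[1, 1] <- Inf
  cfg <- model_config("gcn", hidden_dim = 3, init_seed = 1)
  expect_error(
    train_model(g, cfg, train_config(epochs = 3, lr = 0.01, seed = 1)),
    class = "alngraph_training_error")
})
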