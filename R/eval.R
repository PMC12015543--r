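#' Cross-tabulate binary predictions against truth
#'
#' Positive class = metastasis (1).
#'
#' @param y_true Binary 0/1 truth vector.
#' @param y_hat Binary 0/1 prediction vector of the same length.
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_from_predictions <- function(y_true, y_hat) {
  if (length(y_true) != length(y_hat)) {
    abort("`y_true` and `y_hat` must have the same length.",
          class = "alngraph_parameter_error")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_hat %in% c(0, 1))) {
    abort("Inputs must be binary 0/1.", class = "alngraph_parameter_error")
  }
  confusion_matrix(tp = sum(y_true == 1 & y_hat == 1),
                   fp = sum(y_true == 0 & y_hat == 1),
                   tn = sum(y_true == 0 & y_hat == 0),
                   fn = sum(y_true == 1 & y_hat == 0))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "alngraph_parameter_error")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Threshold classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, accuracy and F1 (harmonic mean of PPV and sensitivity).
#' Metrics whose denominator is zero are reported as NA.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row tibble with `sen`, `spec`, `ppv`, `npv`, `acc`, `f1` and
#'   the four counts.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- safe(cm$tp, cm$tp + cm$fn)
  ppv <- safe(cm$tp, cm$tp + cm$fp)
  f1 <- if (!is.na(sen) && !is.na(ppv) && (sen + ppv) > 0) {
    2 * ppv * sen / (ppv + sen)
  } else NA_real_
  tibble::tibble(
    sen = sen,
    spec = safe(cm$tn, cm$tn + cm$fp),
    ppv = ppv,
    npv = safe(cm$tn, cm$tn + cm$fn),
    acc = safe(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn),
    f1 = f1,
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
}

check_scores <- function(probabilities, y_true, need_both = TRUE) {
  if (length(probabilities) != length(y_true)) {
    abort("Scores and labels must have the same length.",
          class = "alngraph_parameter_error")
  }
  if (!all(y_true %in% c(0, 1))) {
    abort("`y_true` must be binary 0/1.", class = "alngraph_parameter_error")
  }
  if (need_both && length(unique(y_true)) < 2L) {
    abort("`y_true` must contain both classes.",
          class = "alngraph_parameter_error")
  }
}

#' ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (prediction positive when
#' `score >= threshold`), so tied scores enter simultaneously; the AUC is the
#' trapezoidal integral of the resulting curve, which equals the
#' Mann-Whitney rank statistic with tie correction.
#'
#' @param probabilities Numeric scores (higher = more likely metastasis).
#' @param y_true Binary 0/1 labels, both classes present.
#' @return List with `roc_points` (tibble `threshold`, `fpr`, `tpr`,
#'   starting at (0, 0)) and `auc`.
#' @export
roc_auc <- function(probabilities, y_true) {
  check_scores(probabilities, y_true)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  pos <- probabilities[y_true == 1]
  neg <- probabilities[y_true == 0]
  tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = tibble::tibble(threshold = c(Inf, thr),
                                   fpr = fpr, tpr = tpr),
       auc = auc)
}

boot_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(neg))
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap over patients, resampling within each class
#' (class-stratified) so every resample contains both classes.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (>= 100; default 2000).
#' @param seed Integer seed; the interval is reproducible.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `ci_low` and `ci_high`.
#' @export
auc_ci <- function(probabilities, y_true, n_boot = 2000L, seed = 1L,
                   level = 0.95) {
  check_scores(probabilities, y_true)
  if (n_boot < 100L) {
    abort("`n_boot` must be >= 100.", class = "alngraph_parameter_error")
  }
  pos <- probabilities[y_true == 1]
  neg <- probabilities[y_true == 0]
  aucs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      boot_auc(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
    }, numeric(1))
  })
  qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(ci_low = qs[1], ci_high = qs[2])
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct score threshold (prediction
#' positive when `score >= threshold`); average precision is the
#' step-weighted sum `sum_k (R_k - R_{k-1}) P_k`.
#'
#' @inheritParams roc_auc
#' @return List with `pr_points` (tibble `threshold`, `recall`, `precision`)
#'   and `avg_precision`.
#' @export
pr_curve <- function(probabilities, y_true) {
  check_scores(probabilities, y_true, need_both = FALSE)
  if (sum(y_true == 1) == 0L) {
    abort("`y_true` must contain positives.",
          class = "alngraph_parameter_error")
  }
  thr <- sort(unique(probabilities), decreasing = TRUE)
  n_pos <- sum(y_true == 1)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- probabilities >= t
    tp <- sum(pred & y_true == 1)
    tibble::tibble(threshold = t, recall = tp / n_pos,
                   precision = tp / sum(pred))
  })
  ap <- sum(diff(c(0, pts$recall)) * pts$precision)
  list(pr_points = pts, avg_precision = ap)
}

#' Agreement between two models' hard predictions
#'
#' Pearson correlation of the two 0/1 prediction vectors, which equals the
#' phi coefficient of their 2x2 cross-tabulation.
#'
#' @param pred_a,pred_b Equal-length binary prediction vectors, each with
#'   positive variance.
#' @return Scalar correlation in \[-1, 1\].
#' @export
model_agreement <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) {
    abort("Prediction vectors must have the same length.",
          class = "alngraph_parameter_error")
  }
  if (sd(pred_a) == 0 || sd(pred_b) == 0) {
    abort("Prediction vectors must have positive variance.",
          class = "alngraph_parameter_error")
  }
  cor(pred_a, pred_b)
}

#' Pairwise agreement matrix across models
#'
#' @param predictions Named list of binary prediction vectors.
#' @return Tibble in long form with `model_a`, `model_b`, `agreement`.
#' @export
agreement_matrix <- function(predictions) {
  nm <- names(predictions)
  pairs <- expand.grid(model_a = nm, model_b = nm,
                       stringsAsFactors = FALSE)
  pairs$agreement <- mapply(function(a, b) {
    if (a == b) 1 else model_agreement(predictions[[a]], predictions[[b]])
  }, pairs$model_a, pairs$model_b)
  tibble::as_tibble(pairs)
}

#' Evaluate a trained model on a graph
#'
#' Computes per-node probabilities and hard labels (threshold 0.5, ties
#' positive), the confusion matrix and its threshold metrics, the ROC curve
#' with trapezoidal AUC and a class-stratified percentile-bootstrap CI, and
#' the precision-recall curve with average precision.
#'
#' @param model A trained [train_model()] object.
#' @param graph A `patient_graph` to evaluate on.
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @param seed Seed for the bootstrap.
#' @return An object of class `gnn_eval`.
#' @export
evaluate_model <- function(model, graph, n_boot = 2000L, seed = 1L) {
  preds <- predict(model, graph)
  cm <- confusion_from_predictions(preds$aln_status, preds$pred)
  roc <- roc_auc(preds$prob_alnm, preds$aln_status)
  ci <- auc_ci(preds$prob_alnm, preds$aln_status, n_boot = n_boot,
               seed = seed)
  pr <- pr_curve(preds$prob_alnm, preds$aln_status)
  structure(
    list(architecture = model$config$architecture,
         predictions = preds, confusion = cm,
         metrics = classification_metrics(cm),
         roc_points = roc$roc_points, auc = roc$auc,
         auc_ci_low = ci$ci_low, auc_ci_high = ci$ci_high,
         pr_points = pr$pr_points, avg_precision = pr$avg_precision),
    class = "gnn_eval")
}

#' @export
print.gnn_eval <- function(x, ...) {
  cat(sprintf(
    "<gnn_eval> %s: n=%d acc=%.2f auc=%.2f [%.2f-%.2f] sen=%.2f spec=%.2f\n",
    toupper(x$architecture), nrow(x$predictions), x$metrics$acc, x$auc,
    x$auc_ci_low, x$auc_ci_high, x$metrics$sen, x$metrics$spec))
  invisible(x)
}

#' Tidy an evaluation into a long metric table
#'
#' @param x A `gnn_eval`.
#' @param ... Unused.
#' @return Tibble with `metric` and `value` rows (sen, spec, ppv, npv, acc,
#'   f1, auc, auc_ci_low, auc_ci_high, avg_precision).
#' @export
tidy.gnn_eval <- function(x, ...) {
  wide <- glance(x)
  tidyr::pivot_longer(
    dplyr::select(wide, -"architecture", -"n"),
    dplyr::everything(), names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation
#'
#' @param x A `gnn_eval`.
#' @param ... Unused.
#' @return One-row tibble with the architecture, sample size and all metrics.
#' @export
glance.gnn_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(architecture = x$architecture, n = nrow(x$predictions)),
    dplyr::select(x$metrics, "sen", "spec", "ppv", "npv", "acc", "f1"),
    tibble::tibble(auc = x$auc, auc_ci_low = x$auc_ci_low,
                   auc_ci_high = x$auc_ci_high,
                   avg_precision = x$avg_precision))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation result
#'
#' @param object A `gnn_eval`.
#' @param type `"roc"` (default), `"pr"` or `"confusion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gnn_eval <- function(object, type = c("roc", "pr", "confusion"),
                              ...) {
  type <- match.arg(type)
  title <- toupper(object$architecture)
  if (type == "roc") {
    ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "False-positive rate", y = "True-positive rate",
        title = sprintf("%s ROC (AUC %.2f [%.2f-%.2f])", title, object$auc,
                        object$auc_ci_low, object$auc_ci_high))
  } else if (type == "pr") {
    ggplot2::ggplot(object$pr_points,
                    ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("%s precision-recall (AP %.2f)", title,
                        object$avg_precision))
  } else {
    cm <- object$confusion
    df <- tibble::tibble(
      truth = factor(c("ALNM", "ALNM", "non-ALNM", "non-ALNM"),
                     c("ALNM", "non-ALNM")),
      predicted = factor(c("ALNM", "non-ALNM", "ALNM", "non-ALNM"),
                         c("ALNM", "non-ALNM")),
      count = c(cm$tp, cm$fn, cm$fp, cm$tn))
    ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                     fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(x = "Predicted", y = "True",
                    title = sprintf("%s confusion matrix", title))
  }
}

#' Write the full evaluation report to disk
#'
#' Emits flat CSVs (metrics, confusion counts, ROC points, PR points,
#' per-patient predictions) plus a JSON summary, all prefixed by the
#' architecture name.
#'
#' @param eval_obj A `gnn_eval`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the architecture.
#' @return Invisibly, the vector of paths written.
#' @export
write_eval_report <- function(eval_obj, dir, prefix = NULL) {
  stopifnot(inherits(eval_obj, "gnn_eval"))
  if (is.null(prefix)) prefix <- eval_obj$architecture
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  readr::write_csv(glance(eval_obj), p("metrics.csv"))
  cm <- eval_obj$confusion
  readr::write_csv(tibble::tibble(tp = cm$tp, fp = cm$fp, tn = cm$tn,
                                  fn = cm$fn),
                   p("confusion.csv"))
  readr::write_csv(eval_obj$roc_points, p("roc.csv"))
  readr::write_csv(eval_obj$pr_points, p("pr.csv"))
  readr::write_csv(eval_obj$predictions, p("predictions.csv"))
  jsonlite::write_json(
    as.list(glance(eval_obj)), p("summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(vapply(c("metrics.csv", "confusion.csv", "roc.csv", "pr.csv",
                     "predictions.csv", "summary.json"), p, character(1)))
}
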