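# Performance metrics: confusion matrix, per-class precision/recall/F1,
# ROC and precision-recall curves, probability-threshold purity.

# ROC points at every distinct score threshold (predict positive if
# score >= t), plus the (0,0) and (1,1) anchors; trapezoidal AUC.
roc_curve_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  np <- sum(truth); nn <- length(truth) - np
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tpr <- c(0, tp[last] / max(np, 1))
  fpr <- c(0, fp[last] / max(nn, 1))
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  data.frame(fpr = fpr, tpr = tpr)
}

# precision-recall points at the same thresholds; anchored at recall 0 with
# the precision of the strictest threshold.
pr_curve_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  np <- sum(truth)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)
  recall <- tp[last] / max(np, 1)
  precision <- tp[last] / (tp[last] + fp[last])
  data.frame(recall = c(0, recall), precision = c(precision[1], precision))
}

trapezoid_auc <- function(x, y) {
  o <- order(x)
  sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
}

#' Metrics from predicted labels and probabilities
#'
#' Builds the full evaluation report from raw predictions, independent of
#' any model object: K x K confusion matrix (rows = true class), per-class
#' precision/recall/F1/support, accuracy, one-vs-rest ROC and
#' precision-recall curves with trapezoidal AUCs. Classes that are never
#' predicted (or absent) get precision/recall 0 with a `zero_division`
#' flag.
#'
#' @param truth integer true labels (0-based)
#' @param probs `N x K` probability matrix
#' @param class_names length-K class names
#' @param source_ids optional per-sample identifiers (enables
#'   [confusion_cell_examples()])
#' @return object of class `evaluation_report`
#' @export
metrics_from_predictions <- function(truth, probs, class_names,
                                     source_ids = NULL) {
  k <- length(class_names)
  stopifnot(ncol(probs) == k)
  truth <- as.integer(truth)
  pred <- max.col(probs, ties.method = "first") - 1L
  lev <- seq_len(k) - 1L
  confusion <- table(factor(truth, levels = lev),
                     factor(pred, levels = lev))
  confusion <- matrix(as.integer(confusion), k, k,
                      dimnames = list(true = class_names,
                                      predicted = class_names))
  support <- rowSums(confusion)
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  zero_division <- pred_tot == 0 | support == 0
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  roc <- pr <- vector("list", k)
  roc_auc <- pr_auc <- numeric(k)
  for (j in seq_len(k)) {
    bin <- truth == (j - 1L)
    if (all(bin) || !any(bin)) {   # degenerate one-vs-rest task
      roc[[j]] <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
      pr[[j]] <- data.frame(recall = c(0, 1), precision = c(1, 1))
      roc_auc[j] <- NA_real_; pr_auc[j] <- NA_real_
      next
    }
    roc[[j]] <- roc_curve_points(bin, probs[, j])
    pr[[j]] <- pr_curve_points(bin, probs[, j])
    roc_auc[j] <- trapezoid_auc(roc[[j]]$fpr, roc[[j]]$tpr)
    pr_auc[j] <- trapezoid_auc(pr[[j]]$recall, pr[[j]]$precision)
  }
  names(roc) <- names(pr) <- class_names
  per_class <- data.frame(class = class_names, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          roc_auc = roc_auc, pr_auc = pr_auc,
                          zero_division = zero_division,
                          row.names = NULL)
  rep <- list(confusion = confusion, per_class = per_class,
              accuracy = sum(tp) / length(truth),
              roc_points = roc, pr_points = pr,
              roc_auc = roc_auc, pr_auc = pr_auc,
              probabilities = probs, truth = truth, pred = pred,
              class_names = class_names, source_ids = source_ids)
  if (k == 2L) {
    # binary task: expose the positive-class (class 1) AUCs directly
    rep$positive_roc_auc <- roc_auc[2]
    rep$positive_pr_auc <- pr_auc[2]
  }
  structure(rep, class = "evaluation_report")
}

#' Evaluate a model on an image set
#'
#' Runs the model over the (un-augmented, normalized) data and assembles
#' the complete performance report; predicted class is the probability
#' argmax.
#'
#' @param model a `dl_model`
#' @param data an `image_set` matching the model geometry
#' @param normalizer optional `normalization_spec` (defaults to the one
#'   stored in the model)
#' @return an `evaluation_report`
#' @export
evaluate_model <- function(model, data, normalizer = NULL) {
  if (model$spec$n_classes != length(data$class_names))
    stop_dc("model has ", model$spec$n_classes, " classes but data has ",
            length(data$class_names))
  probs <- predict_proba(model, data, normalizer)
  metrics_from_predictions(data$labels, probs, data$class_names,
                           data$source_ids)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d samples, accuracy %.4f\n",
              length(x$truth), x$accuracy))
  print(x$confusion)
  print(x$per_class[, c("class", "precision", "recall", "f1", "support")],
        digits = 4)
  invisible(x)
}

#' Source ids behind one confusion-matrix cell
#'
#' The data behind the interactive confusion matrix: all sample ids with
#' true class `cell[1]` and predicted class `cell[2]` (0-based classes).
#'
#' @param report an `evaluation_report` built with `source_ids`
#' @param cell integer pair `(true_class, predicted_class)`
#' @return character vector of source ids
#' @export
confusion_cell_examples <- function(report, cell) {
  k <- length(report$class_names)
  if (length(cell) != 2L || any(cell < 0L) || any(cell >= k))
    stop_dc("cell must be two 0-based class indices in [0, ", k - 1L, "]")
  if (is.null(report$source_ids))
    stop_dc("report carries no source_ids")
  report$source_ids[report$truth == cell[1] & report$pred == cell[2]]
}

#' Probability-threshold purity of the extreme strata
#'
#' For a binary task, events with positive-class probability strictly
#' above `upper` are called positive and those strictly below `lower`
#' negative; events in between stay unassigned. Returns the fraction of
#' each called stratum that truly belongs to the called class (e.g., how
#' many of the confidently-called T cells are T cells). An empty stratum
#' yields `NA` (undefined), not 0.
#'
#' @param prob_positive per-event probability of the positive class
#' @param labels true labels: logical, or values matched against
#'   `positive`/`negative`
#' @param upper,lower thresholds with `0 <= lower < upper <= 1`
#' @param positive,negative the label values of the two classes (ignored
#'   for logical `labels`)
#' @return list with `above_purity`, `below_purity`, `n_above`, `n_below`,
#'   `n_unassigned`
#' @export
threshold_purity <- function(prob_positive, labels, upper = 0.9, lower = 0.1,
                             positive = TRUE, negative = FALSE) {
  if (lower >= upper) stop_dc("need lower < upper")
  if (lower < 0 || upper > 1) stop_dc("thresholds must lie in [0, 1]")
  stopifnot(length(prob_positive) == length(labels))
  is_pos <- labels == positive
  is_neg <- labels == negative
  above <- prob_positive > upper
  below <- prob_positive < lower
  list(above_purity = if (any(above)) mean(is_pos[above]) else NA_real_,
       below_purity = if (any(below)) mean(is_neg[below]) else NA_real_,
       n_above = sum(above), n_below = sum(below),
       n_unassigned = sum(!above & !below))
}

#' Mean and sample standard deviation
#'
#' Summary used for per-image validation accuracies (reported as
#' mean ± SD). SD uses the sample (n − 1) form and is `NA` for a single
#' value.
#'
#' @param values numeric vector with at least one element
#' @return list with `mean` and `sd`
#' @export
mean_sd <- function(values) {
  if (length(values) == 0L) stop_dc("need at least one value")
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

# ---------------------------------------------------------------------------
# report export

#' Export an evaluation report
#'
#' Writes the per-class metric table as CSV, the confusion matrix as CSV,
#' and the full report (including curve points) as JSON.
#'
#' @param report an `evaluation_report`
#' @param dir output directory
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
write_report <- function(report, dir, prefix = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_per_class.csv"))
  utils::write.csv(report$per_class, p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_confusion.csv"))
  utils::write.csv(as.data.frame(report$confusion), p2)
  p3 <- file.path(dir, paste0(prefix, ".json"))
  out <- list(accuracy = report$accuracy,
              confusion = unname(apply(report$confusion, 1, as.integer,
                                       simplify = FALSE)),
              class_names = report$class_names,
              per_class = report$per_class,
              roc_points = report$roc_points,
              pr_points = report$pr_points)
  jsonlite::write_json(out, p3, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(p1, p2, p3))
}
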