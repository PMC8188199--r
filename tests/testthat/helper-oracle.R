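# Independent brute-force metric oracle: direct counting at every distinct
# threshold, no shared code with the package implementation.
oracle_metrics <- function(truth, probs) {
  k <- ncol(probs)
  pred <- apply(probs, 1, which.max) - 1L
  out <- list()
  for (j in seq_len(k) - 1L) {
    tp <- sum(truth == j & pred == j); fp <- sum(truth != j & pred == j)
    fn <- sum(truth == j & pred != j)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    score <- probs[, j + 1L]; bin <- truth == j
    ths <- sort(unique(score), decreasing = TRUE)
    tpr <- fpr <- recv <- precv <- numeric(length(ths))
    for (t in seq_along(ths)) {
      call_pos <- score >= ths[t]
      tpr[t] <- sum(call_pos & bin) / sum(bin)
      fpr[t] <- sum(call_pos & !bin) / sum(!bin)
      recv[t] <- tpr[t]
      precv[t] <- sum(call_pos & bin) / sum(call_pos)
    }
    xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
    roc_auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
    xs <- c(0, recv); ys <- c(precv[1], precv)
    pr_auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
    out[[j + 1L]] <- c(precision = prec, recall = rec, f1 = f1,
                       support = sum(bin), roc_auc = roc_auc,
                       pr_auc = pr_auc)
  }
  do.call(rbind, out)
}
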