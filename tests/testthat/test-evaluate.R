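
test_that("a perfect predictor yields a diagonal confusion matrix and unit scores", {
  truth <- rep(0:2, each = 4)
  probs <- matrix(0.05, 12, 3)
  probs[cbind(1:12, truth + 1L)] <- 0.9
  rep <- metrics_from_predictions(truth, probs, c("a", "b", "c"))
  expect_equal(unname(diag(rep$confusion)), rep(4L, 3))
  expect_equal(sum(rep$confusion), 12L)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$per_class$f1, rep(1, 3))
  expect_equal(rep$roc_auc, rep(1, 3))
})

test_that("binary counts reproduce hand-computed precision/recall/F1", {
  # TP=8, FP=2, FN=1, TN=9 for the positive class (class 1)
  truth <- c(rep(1L, 9), rep(0L, 11))
  pred <- c(rep(1L, 8), 0L, rep(1L, 2), rep(0L, 9))
  probs <- cbind(1 - pred, pred) * 0.8 + 0.1
  rep <- metrics_from_predictions(truth, probs, c("neg", "pos"))
  expect_equal(rep$per_class$precision[2], 0.8)
  expect_equal(rep$per_class$recall[2], 8 / 9)
  expect_equal(round(rep$per_class$f1[2], 3), 0.842)
  expect_equal(rep$per_class$support, c(11L, 9L))
})

test_that("a constant predictor on a balanced 4-class set scores chance accuracy", {
  truth <- rep(0:3, each = 5)
  probs <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), each = 20), 20, 4)
  rep <- metrics_from_predictions(truth, probs, letters[1:4])
  expect_equal(rep$accuracy, 0.25)
  expect_true(rep$per_class$zero_division[2])   # class b never predicted
  expect_equal(rep$per_class$precision[2], 0)
})

test_that("implementation matches the brute-force oracle on 50 random sets", {
  for (i in 1:50) {
    k <- sample(2:4, 1)
    rp <- random_predictions(n = sample(15:40, 1), k = k, seed = 1000 + i)
    rp$truth[seq_len(k)] <- 0:(k - 1L)      # every class present
    rep <- metrics_from_predictions(rp$truth, rp$probs, letters[seq_len(k)])
    orc <- oracle_metrics(rp$truth, rp$probs)
    expect_equal(rep$per_class$precision, unname(orc[, "precision"]),
                 tolerance = 1e-9)
    expect_equal(rep$per_class$recall, unname(orc[, "recall"]),
                 tolerance = 1e-9)
    expect_equal(rep$per_class$f1, unname(orc[, "f1"]), tolerance = 1e-9)
    expect_equal(rep$per_class$support, unname(orc[, "support"]))
    expect_equal(rep$roc_auc, unname(orc[, "roc_auc"]), tolerance = 1e-9)
    expect_equal(rep$pr_auc, unname(orc[, "pr_auc"]), tolerance = 1e-9)
  }
})

test_that("ROC AUC agrees with pROC and has the expected extremes", {
  skip_if_not_installed("pROC")
  set.seed(7)
  truth <- rep(0:1, each = 50)
  score <- truth + rnorm(100, 0, 0.3)
  probs <- cbind(1 - score, score)
  rep <- metrics_from_predictions(truth, probs, c("n", "p"))
  ref <- as.numeric(suppressMessages(pROC::auc(truth, score)))
  expect_equal(rep$roc_auc[2], ref, tolerance = 1e-9)

  # perfect ranker
  perfect <- cbind(1 - truth, truth)
  expect_equal(metrics_from_predictions(truth, perfect,
                                        c("n", "p"))$roc_auc[2], 1)
  # random ranker approaches 0.5
  set.seed(8)
  rnd <- runif(4000)
  truth_big <- rep(0:1, 2000)
  rep2 <- metrics_from_predictions(truth_big, cbind(1 - rnd, rnd), c("n", "p"))
  expect_lt(abs(rep2$roc_auc[2] - 0.5), 0.05)
})

test_that("accuracy from the confusion matrix equals direct agreement", {
  rp <- random_predictions(60, 3, seed = 77)
  rep <- metrics_from_predictions(rp$truth, rp$probs, letters[1:3])
  pred <- max.col(rp$probs) - 1L
  expect_equal(rep$accuracy, mean(pred == rp$truth))
  expect_equal(unname(rowSums(rep$confusion)),
               as.integer(table(factor(rp$truth, levels = 0:2))))
})

test_that("confusion-cell drill-down returns exactly the matching ids", {
  truth <- c(0L, 1L, 1L)
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.7, 0.3))  # third is an error
  rep <- metrics_from_predictions(truth, probs, c("a", "b"),
                                  source_ids = c("s1", "s2", "s3"))
  expect_equal(confusion_cell_examples(rep, c(1L, 0L)), "s3")
  expect_equal(confusion_cell_examples(rep, c(0L, 0L)), "s1")
  # cells partition the dataset
  total <- sum(vapply(0:1, function(i) sum(vapply(0:1, function(j)
    length(confusion_cell_examples(rep, c(i, j))), numeric(1))), numeric(1)))
  expect_equal(total, 3)
  expect_error(confusion_cell_examples(rep, c(0L, 5L)), "class indices")
})

test_that("threshold purity counts strict strata and flags empty ones", {
  probs <- c(0.95, 0.92, 0.97, 0.85)
  labels <- c("T", "T", "B", "T")
  tp <- threshold_purity(probs, labels, upper = 0.9, lower = 0.1,
                         positive = "T", negative = "B")
  expect_equal(tp$above_purity, 2 / 3)
  expect_equal(tp$n_above, 3L)
  expect_true(is.na(tp$below_purity))     # nothing below 0.1: undefined
  expect_equal(tp$n_unassigned, 1L)

  all_t <- threshold_purity(rep(1, 5), rep("T", 5), 0.9, 0.1,
                            positive = "T", negative = "B")
  expect_equal(all_t$above_purity, 1)
  expect_error(threshold_purity(probs, labels, upper = 0.1, lower = 0.9),
               "lower < upper")
})

test_that("mean_sd uses the sample (n-1) standard deviation", {
  expect_equal(mean_sd(c(1, 1, 1)), list(mean = 1, sd = 0))
  ms <- mean_sd(c(0, 1))
  expect_equal(ms$mean, 0.5)
  expect_equal(round(ms$sd, 4), 0.7071)
  single <- mean_sd(5)
  expect_equal(single$mean, 5)
  expect_true(is.na(single$sd))
  expect_error(mean_sd(numeric(0)), "at least one")
})

test_that("report export writes per-class CSV, confusion CSV, and JSON", {
  rp <- random_predictions(30, 3, seed = 42)
  rp$truth[1:3] <- 0:2
  rep <- metrics_from_predictions(rp$truth, rp$probs, letters[1:3])
  d <- tempfile("report")
  paths <- write_report(rep, d)
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(file.path(d, "evaluation.json"),
                              simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$accuracy)
  unlink(d, recursive = TRUE)
})
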