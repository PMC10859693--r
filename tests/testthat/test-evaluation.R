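test_that("the five criteria match hand arithmetic", {
  perfect <- confusion_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_equal(unname(unlist(perfect)), rep(1, 5))

  m <- confusion_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-12)
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall),
               tolerance = 1e-12)
})

test_that("zero denominators yield NaN with a warning, never 0", {
  expect_warning(m <- confusion_metrics(list(TP = 0, FP = 0, TN = 5,
                                             FN = 3)),
                 "precision undefined")
  expect_true(is.nan(m$precision))
  expect_error(confusion_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "No evaluated")
})

test_that("AUC follows the rank-sum formulation with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2),
                       c("virus", "virus", "host", "host"))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.2),
                       c("virus", "virus", "host", "host"))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10),
                       rep(c("virus", "host"), 5))$auc, 0.5)
  expect_error(roc_auc(1:3 / 3, rep("virus", 3)), "Both classes")
})

test_that("AUC agrees with a brute-force pair loop and with pROC", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 80
      labels <- sample(c("virus", "host"), n, replace = TRUE,
                       prob = c(0.4, 0.6))
      scores <- round(runif(n), 2)  # rounding forces ties
    })
    pos <- which(labels == "virus")
    neg <- which(labels == "host")
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    brute <- tot / (length(pos) * length(neg))
    expect_equal(roc_auc(scores, labels)$auc, brute, tolerance = 1e-12)
    skip_if_not_installed("pROC")
    expect_equal(
      roc_auc(scores, labels)$auc,
      as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("host",
                                                                "virus"),
                                     direction = "<", quiet = TRUE))),
      tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(11, {
    scores <- runif(60)
    labels <- sample(c("virus", "host"), 60, replace = TRUE)
  })
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(qlogis(scores), labels)$auc, a0)
  expect_equal(roc_auc(scores^3 + 2, labels)$auc, a0)
})

test_that("ROC points trace the empirical curve", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c("virus", "virus", "host", "host"))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("evaluation joins on id and enforces integrity", {
  preds <- tibble::tibble(id = sprintf("s%d", 1:6),
                          score = c(0.9, 0.8, 0.7, 0.2, 0.3, 0.1))
  labs <- tibble::tibble(id = sprintf("s%d", 1:6),
                         label = rep(c("virus", "host"), each = 3))
  ev <- evaluate_predictions(preds, labs)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$metrics$n, 6L)

  flipped <- labs
  flipped$label <- rev(labs$label)
  suppressWarnings(ev2 <- evaluate_predictions(preds, flipped))
  expect_equal(ev2$metrics$accuracy, 1 - ev$metrics$accuracy)

  expect_error(evaluate_predictions(preds, labs[1:4, ]), "without labels")
  expect_error(evaluate_predictions(preds, labs[c(1:6, 1), ]),
               "Duplicated")
})

test_that("metric reports serialize to JSON and TSV", {
  preds <- tibble::tibble(id = c("a", "b", "c", "d"),
                          score = c(0.9, 0.6, 0.4, 0.1))
  labs <- tibble::tibble(id = c("a", "b", "c", "d"),
                         label = c("virus", "virus", "host", "host"))
  ev <- evaluate_predictions(preds, labs)
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics(ev, js)
  got <- jsonlite::read_json(js)
  expect_equal(got$accuracy, 1)
  expect_equal(got$TP, 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(ev, tsv)
  expect_equal(read.delim(tsv)$auc, 1)
})

test_that("tidy and autoplot methods expose the results", {
  preds <- tibble::tibble(id = c("a", "b", "c", "d"),
                          score = c(0.9, 0.6, 0.4, 0.1))
  labs <- tibble::tibble(id = c("a", "b", "c", "d"),
                         label = c("virus", "virus", "host", "host"))
  ev <- evaluate_predictions(preds, labs)
  long <- tidy(ev)
  expect_true(all(c("metric", "value") %in% names(long)))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev$roc), "ggplot")
})
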