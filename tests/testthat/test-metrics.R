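test_that("confusion counts match hand examples and the tally oracle", {
  cc <- confusion(c(0, 1), c(0, 1), class_set = c(0, 1))
  expect_equal(unname(cc["0", ]), c(1L, 1L, 0L, 0L))       # TP TN FP FN
  cc2 <- confusion(c(0, 0), c(1, 1), class_set = c(0, 1))
  expect_equal(unname(cc2["0", "TP"]), 0L)
  expect_equal(unname(cc2["0", "FN"]), 2L)
  expect_equal(unname(cc2["1", "FP"]), 2L)
  expect_equal(unname(cc2["1", "TN"]), 0L)
  set.seed(90)
  classes <- letters[1:5]
  yt <- sample(classes, 100, replace = TRUE)
  yp <- sample(classes, 100, replace = TRUE)
  expect_equal(unclass(confusion(yt, yp, classes)),
               oracle_confusion(yt, yp, classes), ignore_attr = TRUE)
  # row sums equal the sample count; TP total = correct predictions
  cc3 <- confusion(yt, yp, classes)
  expect_true(all(rowSums(cc3) == 100))
  expect_equal(sum(cc3[, "TP"]), sum(yt == yp))
  expect_error(confusion(yt, yp[-1], classes), "equal")
  expect_error(confusion(c("a", "z"), c("a", "a"), classes), "class set")
})

test_that("metric formulas reproduce hand-computed binary tables", {
  b <- matrix(c(50L, 40L, 5L, 5L), 1,
              dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  expect_equal(accuracy(b), 0.90)
  b2 <- matrix(c(2L, 3L, 1L, 0L), 1,
               dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  expect_equal(specificity(b2), 3 / 4)
  expect_equal(sensitivity(b2), 1)
  expect_equal(precision(b2), 2 / 3)
  expect_equal(recall(b2), 1)
  expect_equal(f1_score(b2), 0.8)
  # perfect and all-wrong binary classifiers
  yt <- rep(c("p", "n"), each = 4)
  perfect <- metrics_report(yt, yt, c("p", "n"))
  for (k in c("accuracy", "specificity", "precision", "f1", "recall")) {
    expect_equal(perfect[[k]], 1)
  }
  wrong <- confusion(yt, rev(yt), c("p", "n"))
  expect_equal(accuracy(wrong), 0)
})

test_that("micro averaging gives precision = recall = f1 = accuracy", {
  set.seed(91)
  classes <- paste0("c", 1:5)
  for (rep in 1:20) {
    yt <- sample(classes, 40, replace = TRUE)
    yp <- sample(classes, 40, replace = TRUE)
    r <- metrics_report(yt, yp, classes, averaging = "micro")
    acc_pooled <- mean(yt == yp)               # independent pooled count
    expect_equal(r$precision, acc_pooled)
    expect_equal(r$recall, acc_pooled)
    expect_equal(r$f1, acc_pooled)
    expect_equal(r$accuracy, accuracy(confusion(yt, yp, classes)))
  }
})

test_that("micro metrics are invariant to class ordering; macro differs on imbalance", {
  set.seed(92)
  classes <- c("N", "BC", "BM", "CALC", "M")
  yt <- sample(classes, 60, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  yp <- sample(classes, 60, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  r1 <- metrics_report(yt, yp, classes, "micro")
  r2 <- metrics_report(yt, yp, rev(classes), "micro")
  for (k in c("accuracy", "specificity", "precision", "f1", "recall")) {
    expect_equal(r1[[k]], r2[[k]])
  }
  # constructed imbalance where macro and micro disagree
  yt3 <- c(rep("a", 9), "b")
  yp3 <- c(rep("a", 9), "a")
  cc <- confusion(yt3, yp3, c("a", "b"))
  expect_false(isTRUE(all.equal(precision(cc, "micro"),
                                suppressWarnings(precision(cc, "macro")))))
})

test_that("degenerate denominators warn and report zero", {
  cc <- confusion(c("a", "a"), c("a", "a"), c("a", "b"))
  expect_warning(v <- precision(cc, "macro"), "zero denominator")
  expect_true(v >= 0 && v <= 1)
})

test_that("all metrics stay within [0, 1] on random inputs", {
  set.seed(93)
  classes <- letters[1:4]
  for (rep in 1:10) {
    yt <- sample(classes, 30, replace = TRUE)
    yp <- sample(classes, 30, replace = TRUE)
    for (avg in c("micro", "macro")) {
      r <- suppressWarnings(metrics_report(yt, yp, classes, avg))
      vals <- unlist(r[c("accuracy", "specificity", "precision", "f1",
                         "recall", "sensitivity")])
      expect_true(all(vals >= 0 & vals <= 1))
    }
  }
})

test_that("reports serialize to CSV and JSON in fixed key order", {
  d <- withr::local_tempdir()
  r <- metrics_report(c("a", "b", "a"), c("a", "b", "b"), c("a", "b"))
  p1 <- file.path(d, "m.csv"); p2 <- file.path(d, "m.json")
  write_metrics(r, p1); write_metrics(r, p2)
  csv <- read.csv(p1)
  expect_equal(csv$metric, c("accuracy", "specificity", "precision", "f1",
                             "recall", "sensitivity"))
  js <- jsonlite::read_json(p2)
  expect_equal(names(js), csv$metric)
  expect_equal(js$accuracy, r$accuracy)
})
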