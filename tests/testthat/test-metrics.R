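test_that("confusion counts match hand tallies", {
  cm <- confusionCounts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  perfect <- confusionCounts(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(perfect), diag(3L) * 1L)
  empty <- confusionCounts(character(), character(), c("A", "B"))
  expect_equal(sum(empty), 0L)
  expect_error(confusionCounts("A", "Z", classes = c("A", "B")), "outside")
})

test_that("accuracy is trace over total", {
  expect_equal(accuracy(matrix(c(1, 0, 1, 1), 2, 2)), 2 / 3)
  expect_equal(accuracy(diag(4) * 7), 1)
  expect_equal(accuracy(matrix(c(0, 2, 3, 0), 2, 2)), 0)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("macro sensitivity/specificity and BACC match hand computation", {
  cm <- matrix(c(8, 3, 2, 7), 2, 2)   # rows truth: [[8,2],[3,7]]
  ss <- sensitivitySpecificity(cm)
  expect_equal(unname(ss["sensitivity"]), (0.8 + 0.7) / 2)
  expect_equal(unname(ss["specificity"]), (0.7 + 0.8) / 2)
  expect_equal(balancedAccuracy(cm), 0.75)
  expect_equal(balancedAccuracy(diag(2) * 5), 1)
  # always-predict-A on a balanced two-class problem
  cmA <- matrix(c(10, 10, 0, 0), 2, 2)
  ssA <- sensitivitySpecificity(cmA)
  expect_equal(unname(ssA["sensitivity"]), 0.5)   # (1 + 0) / 2
  expect_equal(unname(ssA["specificity"]), 0.5)   # (0 + 1) / 2
  expect_equal(balancedAccuracy(cmA), 0.5)
})

test_that("degenerate classes are excluded with a warning", {
  cm <- matrix(c(5, 0, 2, 0), 2, 2)   # class 2 never true (so class 1 has no negatives)
  expect_warning(expect_warning(ss <- sensitivitySpecificity(cm),
                                "without true samples"),
                 "negative samples")
  expect_equal(unname(ss["sensitivity"]), 5 / 7)
  one <- matrix(4, 1, 1, dimnames = list("A", "A"))   # no negatives at all
  expect_warning(s1 <- sensitivitySpecificity(one), "negative")
  expect_equal(unname(s1["sensitivity"]), 1)
})

test_that("balanced accuracy is invariant to per-class prevalence", {
  # two classes: specificity of one class is the recall of the other,
  # so BACC is exactly prevalence-invariant
  set.seed(3)
  cm <- matrix(sample(1:9, 4, TRUE), 2, 2)
  for (k in list(c(7L, 1L), c(2L, 5L), c(10L, 10L)))
    expect_equal(balancedAccuracy(cm * k), balancedAccuracy(cm))
  # with more classes, per-class recall (and hence macro recall) stays
  # prevalence-free
  cm3 <- matrix(sample(1:9, 9, TRUE), 3, 3)
  expect_equal(unname(sensitivitySpecificity(cm3 * c(1L, 7L, 3L))["sensitivity"]),
               unname(sensitivitySpecificity(cm3)["sensitivity"]))
})

test_that("metrics on merged batches equal metrics on summed confusion matrices", {
  set.seed(4)
  t1 <- sample(c("A", "B", "C"), 30, TRUE); p1 <- sample(c("A", "B", "C"), 30, TRUE)
  t2 <- sample(c("A", "B", "C"), 20, TRUE); p2 <- sample(c("A", "B", "C"), 20, TRUE)
  cls <- c("A", "B", "C")
  merged <- confusionCounts(c(t1, t2), c(p1, p2), cls)
  summed <- confusionCounts(t1, p1, cls) + confusionCounts(t2, p2, cls)
  expect_equal(merged, summed)
  expect_equal(balancedAccuracy(merged), balancedAccuracy(summed))
})

test_that("accuracy equals balanced accuracy on balanced confusion structures", {
  cm <- matrix(c(6, 2, 2, 6), 2, 2)     # symmetric, balanced prevalence
  expect_equal(accuracy(cm), balancedAccuracy(cm))
})

test_that("macro AUC matches rank counting and an independent implementation", {
  # one-hot scores of the truth are a perfect ranking
  truth <- c("A", "A", "B", "B")
  perfect <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  colnames(perfect) <- c("A", "B")
  expect_equal(aucMacro(truth, perfect), 1)
  # one inversion among 4 samples: per-class AUC 3/4
  scoresB <- c(0.1, 0.6, 0.4, 0.9)
  scores <- cbind(A = 1 - scoresB, B = scoresB)
  expect_equal(aucMacro(truth, scores), 0.75)
  # ties contribute 1/2
  tied <- cbind(A = c(0.5, 0.5, 0.5, 0.5), B = c(0.5, 0.5, 0.5, 0.5))
  expect_equal(aucMacro(truth, tied), 0.5)
  # against pROC on random scores
  skip_if_not_installed("pROC")
  set.seed(5)
  truth2 <- sample(c("A", "B", "C"), 60, TRUE)
  sc <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("A", "B", "C")))
  ours <- aucMacro(truth2, sc)
  ref <- mean(sapply(c("A", "B", "C"), function(cl)
    as.numeric(pROC::auc(pROC::roc(truth2 == cl, sc[, cl], quiet = TRUE,
                                   direction = "<")))))
  expect_equal(ours, ref, tolerance = 1e-10)
  # class absent from truth is excluded with a warning
  sc2 <- sc; truth3 <- sub("C", "B", truth2)
  expect_warning(a <- aucMacro(truth3, sc2), "excluded")
  expect_true(a >= 0 && a <= 1)
})

test_that("the full report is internally consistent and serializes", {
  set.seed(6)
  truth <- sample(c("A", "B", "C"), 50, TRUE)
  sc <- matrix(runif(150), 50, 3, dimnames = list(NULL, c("A", "B", "C")))
  pred <- colnames(sc)[max.col(sc)]
  rep <- suppressWarnings(metricsReport(truth, pred, sc))
  expect_equal(rep@bacc, (rep@sensitivity + rep@specificity) / 2)
  expect_equal(rep@baccRecall, rep@sensitivity)
  expect_equal(rep@accuracy,
               accuracy(confusionCounts(truth, pred, c("A", "B", "C"))))
  expect_true(all(c(rep@accuracy, rep@bacc, rep@auc) >= 0 &
                  c(rep@accuracy, rep@bacc, rep@auc) <= 1))
  f <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  writeMetrics(rep, f, fc)
  back <- jsonlite::read_json(f)
  expect_equal(back$bacc, rep@bacc, tolerance = 1e-12)
  cmBack <- as.matrix(utils::read.csv(fc, row.names = 1))
  expect_equal(unname(cmBack), unname(rep@confusion))
})
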