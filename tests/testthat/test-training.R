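# small deterministic dataset builders used across training tests
toyDataset <- function(n = 60, C = 2, size = 16, lambda = 0, seed = 1) {
  generateDataset(synthConfig(nSamples = n, nClasses = C, imageSize = size,
                              metaFields = list(sex = c("female", "male")),
                              metaEffect = lambda, noiseSd = 0.03, seed = seed))
}

toyModel <- function(data, fusionKind = "none", kImg = 8L, dropout = 0,
                     seed = 1L) {
  sch <- buildSchema(data@meta)
  bb <- tinyDenseBackbone(kImg, seed = seed)
  fus <- switch(fusionKind,
                none = noneFusion(), concat = concatFusion(),
                mdnet = mdnetParams(dMeta(sch), kImg, seed = seed),
                metablock = metaBlockParams(dMeta(sch), kImg, seed = seed),
                metanet = metaNetParams(dMeta(sch), kImg, seed = seed))
  metaFuseModel(bb, fus, levels(data@labels),
                schema = if (fusionKind == "none") NULL else sch,
                dropout = dropout, seed = seed)
}

test_that("splitting is exhaustive, deterministic and stratified", {
  d <- toyDataset(n = 100, C = 2)
  sp <- splitDataset(d, 0.75, seed = 3)
  expect_equal(length(sp$train), 75L)
  expect_equal(length(sp$test), 25L)
  sp2 <- splitDataset(d, 0.75, seed = 3)
  expect_identical(as.character(sp$train@labels), as.character(sp2$train@labels))
  expect_identical(sp$train@images, sp2$train@images)

  # stratified 3:1 split of 40 A + 20 B gives 30/10 and 15/5
  labels <- rep(c("A", "B"), c(40, 20))
  imgs <- array(runif(8 * 8 * 3 * 60), c(8, 8, 3, 60))
  d2 <- lesionDataset(imgs, data.frame(sex = rep("f", 60)), labels)
  sp3 <- splitDataset(d2, 0.75, seed = 1, stratify = TRUE)
  expect_equal(as.integer(table(sp3$train@labels)[c("A", "B")]), c(30L, 15L))
  expect_equal(as.integer(table(sp3$test@labels)[c("A", "B")]), c(10L, 5L))

  expect_error(splitDataset(d, 1.5), "between 0 and 1")
  expect_error(splitDataset(d, 0), "between 0 and 1")
})

test_that("augmentation honours identity, involution and determinism contracts", {
  set.seed(10)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  # all probabilities and jitters zero: exact identity
  expect_identical(augmentImage(img, 0, 0, 0, 0, 0), img)
  # horizontal flip applied twice restores the image
  once <- augmentImage(img, hFlip = 1, vFlip = 0, brightness = 0,
                       contrast = 0, saturation = 0)
  twice <- augmentImage(once, hFlip = 1, vFlip = 0, brightness = 0,
                        contrast = 0, saturation = 0)
  expect_identical(twice, img)
  expect_false(identical(once, img))
  # byte-identical under a fixed RNG state, dimensions always unchanged
  set.seed(99); a <- augmentImage(img)
  set.seed(99); b <- augmentImage(img)
  expect_identical(a, b)
  expect_equal(dim(a), dim(img))
  expect_true(min(a) >= 0 && max(a) <= 1)
})

test_that("plateau halving triggers exactly after the patience window", {
  cfg <- trainConfig()
  mkHist <- function(vb, lr) data.frame(epoch = seq_along(vb),
                                        loss = 1, lr = lr, valBacc = vb)
  # improvement at epoch 1, then 10 flat epochs -> one halving
  h <- mkHist(c(0.6, rep(0.6, 10)), rep(1e-3, 11))
  expect_equal(lrScheduleStep(h, 1e-3, cfg), 5e-4)
  # improvement at epoch 9 of the window resets the counter
  vb <- c(0.6, rep(0.6, 7), 0.65, 0.65)
  expect_equal(lrScheduleStep(mkHist(vb, rep(1e-3, 10)), 1e-3, cfg), 1e-3)
  # fewer than patience epochs at the current rate: no second cut yet
  h2 <- mkHist(c(0.6, rep(0.6, 12)), c(rep(1e-3, 11), rep(5e-4, 2)))
  expect_equal(lrScheduleStep(h2, 5e-4, cfg), 5e-4)
  # two full plateaus -> lr0 / 4
  h3 <- mkHist(c(0.6, rep(0.6, 20)), c(rep(1e-3, 11), rep(5e-4, 10)))
  expect_equal(lrScheduleStep(h3, 5e-4, cfg), 2.5e-4)
  # n triggered reductions compose to lr0 * factor^n exactly
  lr <- 1e-3
  for (n in 1:4) lr <- lr * cfg$lrFactor
  expect_equal(lr, 1e-3 * 0.5^4)
})

test_that("early stopping waits for the full patience window", {
  cfg <- trainConfig()
  mkHist <- function(vb) data.frame(epoch = seq_along(vb), loss = 1,
                                    lr = 1e-3, valBacc = vb)
  expect_true(earlyStopCheck(mkHist(c(0.7, rep(0.7, 15))), cfg))
  expect_false(earlyStopCheck(mkHist(c(0.7, rep(0.7, 14))), cfg))
  expect_false(earlyStopCheck(mkHist(seq(0.5, 0.8, length.out = 40)), cfg))
  # an improvement at epoch 14 resets the counter
  vb <- c(0.7, rep(0.7, 13), 0.75)
  expect_false(earlyStopCheck(mkHist(vb), cfg))
})

test_that("training drives a separable toy task to perfect training accuracy", {
  d <- toyDataset(n = 60, C = 2, seed = 5)
  m <- toyModel(d, "none", seed = 5)
  cfg <- trainConfig(seed = 5, maxEpochs = 60, augment = FALSE,
                     batchSize = 15)
  fit <- fitModel(m, d, cfg)
  train <- evaluateModel(fit$model, d)
  expect_equal(train@accuracy, 1.0)
  expect_lte(fit$stoppedEpoch, 60L)
  # learning rate never increases and loss history is recorded per epoch
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_equal(fit$history$epoch, seq_len(nrow(fit$history)))
})

test_that("zero-epoch training returns the initial model and empty history", {
  d <- toyDataset(n = 20, C = 2, seed = 6)
  m <- toyModel(d, "concat", seed = 6)
  fit <- fitModel(m, d, trainConfig(seed = 6, maxEpochs = 0))
  expect_equal(nrow(fit$history), 0L)
  expect_equal(predictProbs(fit$model, d), predictProbs(m, d))
})

test_that("identical seeds reproduce the identical training history", {
  d <- toyDataset(n = 40, C = 2, seed = 7)
  m <- toyModel(d, "mdnet", dropout = 0.5, seed = 7)
  cfg <- trainConfig(seed = 7, maxEpochs = 6, batchSize = 10)
  f1 <- fitModel(m, d, cfg)
  f2 <- fitModel(m, d, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(predictProbs(f1$model, d), predictProbs(f2$model, d))
})

test_that("evaluation is order-invariant and consistent with the metrics module", {
  d <- toyDataset(n = 40, C = 2, seed = 8)
  m <- toyModel(d, "metablock", seed = 8)
  fit <- fitModel(m, d, trainConfig(seed = 8, maxEpochs = 4, batchSize = 10))
  rep1 <- evaluateModel(fit$model, d)
  probs <- predictProbs(fit$model, d)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  expect_equal(rep1@bacc, balancedAccuracy(
    confusionCounts(as.character(d@labels), pred, levels(d@labels))))
  perm <- sample(length(d))
  rep2 <- evaluateModel(fit$model, d[perm])
  expect_equal(rep2@confusion, rep1@confusion)
  expect_equal(rep2@bacc, rep1@bacc)
  expect_error(evaluateModel(fit$model, d[integer(0)]), "empty")
})

test_that("checkpoints round trip the full assembly with its manifest", {
  d <- toyDataset(n = 20, C = 2, seed = 9)
  m <- toyModel(d, "mdnet", seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f, config = trainConfig(seed = 9))
  manifest <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(manifest$k_img, 8L)
  expect_equal(manifest$fusion, "MDNetParams")
  expect_equal(manifest$schema_hash, schemaHash(m@schema))
  m2 <- loadCheckpoint(f)
  expect_equal(predictProbs(m2, d), predictProbs(m, d))
  expect_equal(attr(m2, "config")$seed, 9L)
})

test_that("configuration and assembly contracts are validated", {
  expect_error(trainConfig(lrFactor = 1.5))
  expect_error(trainConfig(batchSize = 0))
  d <- toyDataset(n = 20, C = 2, seed = 10)
  bb <- tinyDenseBackbone(8)
  sch <- buildSchema(d@meta)
  expect_error(metaFuseModel(bb, mdnetParams(dMeta(sch), 8), levels(d@labels),
                             schema = NULL), "schema")
  m <- toyModel(d, "none")
  bad <- lesionDataset(d@images, d@meta, rep(c("x", "y"), 10))
  expect_error(fitModel(m, bad, trainConfig(maxEpochs = 1)), "class set")
})
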