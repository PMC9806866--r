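mkBlock <- function(Wf, w0f, Wg, w0g)
  new("MetaBlockParams", Wf = Wf, Wg = Wg, w0f = w0f, w0g = w0g)

test_that("gateScale and gateShift are the affine metadata maps", {
  p <- mkBlock(Wf = matrix(c(1, 2), 2, 1), w0f = 0.5,
               Wg = matrix(c(3, -1), 2, 1), w0g = -0.25)
  expect_equal(gateScale(c(1, 0), p), 1.5)
  expect_equal(gateShift(c(0, 1), p), -1.25)
  # bias-only when the metadata vector is all zero
  expect_equal(gateScale(c(0, 0), p), 0.5)
  expect_equal(gateShift(c(0, 0), p), -0.25)
  # all-zero parameters give the zero vector
  z <- metaBlockParams(2, 3, zero = TRUE)
  expect_equal(gateScale(c(1, 0), z), rep(0, 3))

  # random small-integer instance against an explicit double loop
  set.seed(7)
  Wf <- matrix(sample(-3:3, 8, TRUE), 4, 2)
  w0f <- sample(-2:2, 2, TRUE)
  p2 <- mkBlock(Wf, as.numeric(w0f), Wf * 0, numeric(2))
  m <- c(0, 1, 0, 0)
  manual <- numeric(2)
  for (c in 1:2) {
    manual[c] <- w0f[c]
    for (j in 1:4) manual[c] <- manual[c] + m[j] * Wf[j, c]
  }
  expect_equal(gateScale(m, p2), manual)
})

test_that("tanh gate scales per channel and stays strictly inside (-1, 1)", {
  x <- array(1, c(1, 1, 1, 1))
  expect_equal(tanhGate(x, 1)[1], tanh(1), tolerance = 1e-12)
  expect_equal(tanhGate(x, 0)[1], 0)
  set.seed(1)
  big <- randomFeatureMap(5, 5, 4, 3) * 3
  out <- tanhGate(big, runif(4, -2, 2))
  expect_true(max(abs(out)) < 1)
  expect_equal(dim(out), dim(big))
})

test_that("sigmoid gate shifts per channel and stays strictly inside (0, 1)", {
  t1 <- array(tanh(1), c(1, 1, 1, 1))
  expect_equal(sigmoidGate(t1, 0)[1], 1 / (1 + exp(-tanh(1))), tolerance = 1e-12)
  expect_equal(sigmoidGate(array(0, c(2, 2, 1, 1)), 0)[1, 1, 1, 1], 0.5)
  # monotone saturation toward 1 as the shift grows
  vals <- sapply(c(0, 2, 5, 20), function(g)
    sigmoidGate(array(0.3, c(1, 1, 1, 1)), g)[1])
  expect_true(all(diff(vals) > 0) && all(vals < 1) && vals[4] > 0.999)
  set.seed(2)
  out <- sigmoidGate(randomFeatureMap(4, 4, 3, 2), rnorm(3))
  expect_true(min(out) > 0 && max(out) < 1)
})

test_that("metaBlockForward composes the gates and matches the scalar-loop oracle", {
  # all-zero parameters: sigma(tanh(0) + 0) = 0.5 everywhere
  z <- metaBlockParams(3, 2, zero = TRUE)
  x <- randomFeatureMap(4, 4, 2, 2)
  expect_equal(as.vector(metaBlockForward(x, matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE), z)),
               rep(0.5, length(x)))
  # scalar case: d_meta = k_img = h = w = 1
  p <- mkBlock(matrix(1, 1, 1), 0, matrix(0, 1, 1), 0)
  out <- metaBlockForward(array(1, c(1, 1, 1, 1)), 1, p)
  expect_equal(out[1], 1 / (1 + exp(-tanh(1))), tolerance = 1e-12)
  expect_equal(out[1], 0.6817, tolerance = 1e-4)
  # equivalence with the quadruple-nested scalar loop
  set.seed(11)
  for (rep in 1:5) {
    x <- randomFeatureMap(4, 4, 3, 2)
    M <- matrix(rnorm(2 * 5), 2, 5)
    p <- metaBlockParams(5, 3, seed = rep)
    got <- metaBlockForward(x, M, p)
    want <- metaBlockLoopOracle(x, M, p@Wf, p@w0f, p@Wg, p@w0g)
    expect_lt(relErr(got, want), 1e-10)
    expect_equal(dim(got), dim(x))
    expect_true(min(got) > 0 && max(got) < 1)
  }
})

test_that("metaNetForward reweights channels and matches the scalar-chain oracle", {
  x <- randomFeatureMap(3, 3, 4, 2)
  z <- metaNetParams(2, 4, zero = TRUE)
  M <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(metaNetForward(x, M, z), x * 0.5)   # sigma(0) = 0.5 per channel
  expect_equal(metaNetForward(x * 0, M, metaNetParams(2, 4, seed = 3)),
               x * 0)                              # multiplicative absorption
  # hand-set 2 -> 2 -> 1 chain
  p <- new("MetaNetParams", W1 = matrix(c(1, -1, 0.5, 2), 2, 2), b1 = c(0.1, -0.2),
           W2 = matrix(c(1.5, -0.7), 2, 1), b2 = 0.3)
  m <- c(1, 0)
  a1 <- c(1 * 1 + 0.1, 0.5 * 1 - 0.2)
  r <- pmax(a1, 0)
  s <- 1 / (1 + exp(-(r[1] * 1.5 + r[2] * -0.7 + 0.3)))
  x1 <- array(2, c(1, 1, 1, 1))
  expect_equal(metaNetForward(x1, m, p)[1], 2 * s, tolerance = 1e-12)
  # loop-oracle equivalence, range of scales, sign/magnitude preservation
  set.seed(21)
  for (rep in 1:5) {
    x <- randomFeatureMap(4, 4, 3, 2)
    M <- matrix(rnorm(2 * 5), 2, 5)
    p <- metaNetParams(5, 3, seed = 100 + rep)
    got <- metaNetForward(x, M, p)
    want <- metaNetLoopOracle(x, M, p@W1, p@b1, p@W2, p@b2)
    expect_lt(relErr(got, want), 1e-10)
    expect_true(all(abs(got) <= abs(x)))
    expect_true(all(sign(got) == sign(x) | got == 0))
    s <- metaNetScales(M, p)
    expect_true(min(s) > 0 && max(s) < 1)
  }
})

test_that("mdnetFuse pools, projects and concatenates both streams", {
  set.seed(31)
  x <- randomFeatureMap(4, 4, 6, 2)
  M <- matrix(rnorm(2 * 3), 2, 3)
  # all-zero params with zero projections give the zero vector
  z <- mdnetParams(3, 6, dFuse = 2, zero = TRUE)
  expect_equal(mdnetFuse(x, M, z), matrix(0, 2, 4))
  # identity projections (dFuse = kImg) expose the pooled block outputs
  p <- mdnetParams(3, 6, dFuse = 6, seed = 5)
  p@Pnet <- diag(6); p@bnet <- numeric(6)
  p@Pblock <- diag(6); p@bblock <- numeric(6)
  got <- mdnetFuse(x, M, p)
  want <- cbind(globalAvgPool(metaNetForward(x, M, p@metanet)),
                globalAvgPool(metaBlockForward(x, M, p@metablock)))
  expect_equal(got, want)
  # random instance against the composition of loop oracles
  p2 <- mdnetParams(3, 6, seed = 6)
  got2 <- mdnetFuse(x, M, p2)
  pn <- poolLoopOracle(metaNetLoopOracle(x, M, p2@metanet@W1, p2@metanet@b1,
                                         p2@metanet@W2, p2@metanet@b2))
  pb <- poolLoopOracle(metaBlockLoopOracle(x, M, p2@metablock@Wf, p2@metablock@w0f,
                                           p2@metablock@Wg, p2@metablock@w0g))
  want2 <- cbind(pn %*% p2@Pnet + rep(p2@bnet, each = 2),
                 pb %*% p2@Pblock + rep(p2@bblock, each = 2))
  expect_lt(relErr(got2, want2), 1e-10)
  expect_equal(ncol(got2), 2L * p2@dFuse)
})

test_that("concatFuse appends the metadata to spatially averaged channels", {
  set.seed(41)
  x <- randomFeatureMap(3, 5, 4, 2)
  M <- matrix(c(1, 0, 0, 0), 2, 2)
  out <- concatFuse(x, M)
  expect_equal(dim(out), c(2L, 6L))
  expect_equal(out[, 5:6], M)
  expect_equal(out[, 1:4], poolLoopOracle(x))
  expect_equal(concatFuse(x, M * 0)[, 5:6], matrix(0, 2, 2))
})

test_that("nonzero fusion parameters make outputs metadata-sensitive", {
  set.seed(51)
  x <- randomFeatureMap(4, 4, 3, 1)
  m1 <- c(1, 0); m2 <- c(0, 1)
  pb <- metaBlockParams(2, 3, seed = 9)
  pn <- metaNetParams(2, 3, seed = 9)
  pn@b1 <- abs(pn@b1) + 0.1   # keep the hidden ReLU units alive
  expect_false(isTRUE(all.equal(metaBlockForward(x, m1, pb),
                                metaBlockForward(x, m2, pb))))
  expect_false(isTRUE(all.equal(metaNetForward(x, m1, pn),
                                metaNetForward(x, m2, pn))))
})

test_that("batch processing equals stacking per-sample results", {
  set.seed(61)
  x <- randomFeatureMap(4, 4, 3, 4)
  M <- matrix(rnorm(4 * 2), 4, 2)
  for (p in list(metaBlockParams(2, 3, seed = 1), metaNetParams(2, 3, seed = 1),
                 mdnetParams(2, 3, seed = 1), concatFusion(), noneFusion())) {
    batch <- fuseFeatures(p, x, M)
    for (i in 1:4) {
      single <- fuseFeatures(p, x[, , , i, drop = FALSE], M[i, , drop = FALSE])
      expect_equal(batch[i, ], single[1, ], tolerance = 1e-12)
    }
  }
})

test_that("shape mismatches are rejected", {
  x <- randomFeatureMap(2, 2, 3, 1)
  p <- metaBlockParams(2, 4)    # k_img = 4 but map has 3 channels
  expect_error(metaBlockForward(x, c(1, 0), p), "channel")
  expect_error(tanhGate(x, c(1, 2)), "channels")
  expect_error(gateScale(c(1, 0, 0), metaBlockParams(2, 3)), "d_meta")
  expect_error(metaNetForward(x, c(1, 0, 0), metaNetParams(2, 3)), "d_meta")
})
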