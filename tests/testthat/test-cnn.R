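test_that("layer shape arithmetic follows valid-convolution rules", {
  cfg <- cnnConfig(inputResolution = 28)
  m <- buildModel(cfg)
  # conv output 24x24x15, parameter count 5*5*3*15 + 15 = 1140
  expect_identical(dim(m@params$Wc), c(5L, 5L, 3L, 15L))
  expect_identical(length(m@params$Wc) + length(m@params$bc), 1140L)
  set.seed(1)
  x <- array(runif(28 * 28 * 3 * 2), c(28, 28, 3, 2))
  fw <- ctgcnn:::.cnnForward(m@params, cfg, x)
  expect_identical(dim(fw$z1), c(24L, 24L, 15L, 2L))
  expect_identical(fw$poolDim, c(12L, 12L, 15L, 2L))
  expect_identical(nrow(fw$X1), 12L * 12L * 15L)
  # an input width whose post-convolution size cannot be pooled is refused
  expect_error(cnnConfig(inputResolution = 28, kernelSize = 4),
               "not divisible")
})

test_that("cross-channel normalisation evaluates its formula", {
  a <- array(runif(2 * 2 * 3), c(2, 2, 3))
  # alpha = 0, K = 2: every output is input / 2^0.75
  expect_equal(crossChannelNormalize(a, alpha = 0, k = 2, beta = 0.75),
               a / 2^0.75, tolerance = 1e-12)
  # alpha = 0, K = 1: identity
  expect_equal(crossChannelNormalize(a, alpha = 0, k = 1), a,
               tolerance = 1e-12)
  # single channel, unit activation, window 1: 1/(2.001)^0.75
  one <- array(1, c(1, 1, 1))
  expect_equal(as.numeric(crossChannelNormalize(one, alpha = 1e-3, k = 2,
                                                beta = 0.75, window = 1)),
               1 / 2.001^0.75, tolerance = 1e-12)
  expect_error(crossChannelNormalize(a, k = 0), "positive")
})

test_that("augmentation is deterministic in eval mode and seeded in train mode", {
  cfg <- cnnConfig(inputResolution = 16, seed = 3)
  set.seed(1)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  mu <- array(0.5, c(16, 16, 3))
  e1 <- augment(x, mu, "eval", cfg)
  e2 <- augment(x, mu, "eval", cfg)
  expect_identical(e1, e2)
  expect_equal(e1, x - 0.5, tolerance = 1e-15)  # centre path is exact
  set.seed(7); t1 <- augment(x, mu, "train", cfg)
  set.seed(7); t2 <- augment(x, mu, "train", cfg)
  expect_identical(t1, t2)
  set.seed(8); t3 <- augment(x, mu, "train", cfg)
  expect_false(identical(t1, t3))
  expect_error(augment(x, array(0, c(8, 8, 3)), "eval", cfg), "mismatch")
})

test_that("zero-centering gives the training set per-pixel mean zero", {
  set <- randomImageSet(10, 10, res = 16, seed = 2)
  x <- imageArray(set)
  mu <- array(rowMeans(matrix(x, ncol = 20)), c(16, 16, 3))
  centred <- augment(x, mu, "eval", cnnConfig(inputResolution = 16))
  perPixelMean <- rowMeans(matrix(centred, ncol = 20))
  expect_lt(max(abs(perPixelMean)), 1e-6)
})

test_that("softmax outputs are normalised probabilities with correct saturation", {
  expect_equal(as.numeric(ctgcnn:::.softmax(matrix(c(0, 0)))), c(0.5, 0.5))
  p <- ctgcnn:::.softmax(matrix(c(10, -10)))
  expect_gt(p[1], 0.999)
  set.seed(5)
  z <- matrix(rnorm(2 * 40, sd = 5), 2)
  p <- ctgcnn:::.softmax(z)
  expect_equal(colSums(p), rep(1, 40), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("analytic gradients match central finite differences on a toy net", {
  cfg <- toyCnnConfig(seed = 11)
  m <- buildModel(cfg)
  set.seed(42)
  x <- array(runif(6 * 6 * 1 * 3), c(6, 6, 1, 3))
  y <- ctgcnn:::.oneHot(c("normal", "pathological", "normal"))
  dm <- matrix(runif(4 * 3) >= cfg@dropoutP, 4)
  lg <- ctgcnn:::.cnnLossGrad(m@params, cfg, x, y, train = TRUE, dropMask = dm)
  eps <- 1e-5
  worst <- 0
  for (p in names(m@params)) {
    th <- m@params[[p]]
    for (i in seq_along(th)) {
      pp <- m@params; pp[[p]][i] <- th[i] + eps
      lp <- ctgcnn:::.cnnLossGrad(pp, cfg, x, y, TRUE, dm)$loss
      pp[[p]][i] <- th[i] - eps
      lm <- ctgcnn:::.cnnLossGrad(pp, cfg, x, y, TRUE, dm)$loss
      gn <- (lp - lm) / (2 * eps)
      ga <- lg$grads[[p]][i]
      worst <- max(worst, abs(ga - gn) / max(1e-8, abs(ga) + abs(gn)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the learning-rate schedule drops by the factor every period", {
  cfg <- cnnConfig()
  expect_equal(ctgcnn:::.lrAt(cfg, 1), 0.01)
  expect_equal(ctgcnn:::.lrAt(cfg, 10), 0.01)
  expect_equal(ctgcnn:::.lrAt(cfg, 11), 0.001)
  expect_equal(ctgcnn:::.lrAt(cfg, 20), 0.001)
  expect_equal(ctgcnn:::.lrAt(cfg, 21), 1e-4)
})

test_that("a zero learning rate with zero L2 leaves the weights unchanged", {
  cfg <- cnnConfig(inputResolution = 6, kernelSize = 3, numFilters = 2,
                   fcWidth = 4, seed = 2, initialLr = 0, l2Factor = 0,
                   maxEpochs = 2, miniBatch = 4)
  m <- buildModel(cfg)
  set <- randomImageSet(4, 4, res = 6, seed = 3)
  trained <- trainModel(m, set)
  for (p in names(m@params))
    expect_identical(trained@params[[p]], m@params[[p]])
})

test_that("training is seeded-reproducible and eval prediction deterministic", {
  cfg <- cnnConfig(inputResolution = 16, numFilters = 4, fcWidth = 8,
                   maxEpochs = 2, miniBatch = 5, seed = 21)
  set <- randomImageSet(8, 8, res = 16, seed = 4)
  m1 <- trainModel(buildModel(cfg), set)
  m2 <- trainModel(buildModel(cfg), set)
  expect_identical(m1@params, m2@params)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  p1 <- predict(m1, set)
  p2 <- predict(m1, set)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 16), tolerance = 1e-12)
  expect_identical(colnames(p1), c("normal", "pathological"))
  # resolution mismatch is a shape error
  expect_error(predict(m1, randomImageSet(2, 2, res = 8)), "shape")
})

test_that("dropout only acts during training", {
  cfg <- cnnConfig(inputResolution = 16, numFilters = 3, fcWidth = 50,
                   seed = 5)
  m <- buildModel(cfg)
  set.seed(9)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  f1 <- ctgcnn:::.cnnForward(m@params, cfg, x, train = FALSE)
  f2 <- ctgcnn:::.cnnForward(m@params, cfg, x, train = FALSE)
  expect_identical(f1$prob, f2$prob)
  expect_null(f1$dropMask)
  set.seed(10)
  f3 <- ctgcnn:::.cnnForward(m@params, cfg, x, train = TRUE)
  expect_false(is.null(f3$dropMask))
  expect_false(identical(f3$hd, f1$hd))
})
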