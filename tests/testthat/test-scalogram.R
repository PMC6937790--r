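test_that("sampled mother wavelets satisfy admissibility and refine consistently", {
  for (fam in c("db2", "sym2")) {
    w <- motherWavelet(fam, 1024)
    dx <- w$x[2] - w$x[1]
    expect_lt(abs(sum(w$psi) * dx), 1e-6)
    expect_gte(length(w$x), 1024)
  }
  # refinement convergence: coarse and fine grids agree on common points
  w1 <- motherWavelet("db2", 256)
  w2 <- motherWavelet("db2", 2048)
  step <- (length(w2$x) - 1) / (length(w1$x) - 1)
  common <- w2$psi[seq(1, length(w2$x), by = step)]
  expect_lt(sqrt(mean((w1$psi - common)^2)), 1e-3)
  expect_error(motherWavelet("db9"), "arg")
})

test_that("CWT matches the direct-summation oracle on short signals", {
  set.seed(11)
  for (fam in c("db2", "sym2")) {
    x <- 140 + 10 * sin(2 * pi * seq_len(300) / 25) + rnorm(300)
    sc <- cwtCoefficients(cleanSig(x), fam, 4)
    expect_identical(dim(coeffs(sc)), c(16L, 300L))
    ora <- cwtOracle(x, 4, fam, 4)
    expect_lt(max(abs(coeffs(sc) - ora)) / max(abs(ora)), 1e-10)
  }
})

test_that("CWT is linear and rejects degenerate scales", {
  set.seed(2)
  x <- 120 + cumsum(rnorm(200))
  a <- coeffs(cwtCoefficients(rawRec(x), "db2", 4))
  b <- coeffs(cwtCoefficients(rawRec(2 * x), "db2", 4))
  expect_equal(b, 2 * a, tolerance = 1e-12)
  z <- coeffs(cwtCoefficients(rawRec(x * 0), "db2", 4))
  expect_true(all(z == 0))
  expect_error(cwtCoefficients(cleanSig(x), "db2", 0), "scale")
})

test_that("a unit impulse reproduces the scaled kernel (closed form)", {
  n <- 400
  x <- numeric(n); x[200] <- 1
  sc <- cwtCoefficients(rawRec(x), "db2", 4)
  ora <- cwtOracle(x, 4, "db2", 4)
  co <- coeffs(sc)
  expect_lt(max(abs(co - ora)), 1e-14)
  # for a delta input the tau-profile of each row is the reversed kernel:
  # coef[s, tau] is nonzero only for tau in (impulse - 3s, impulse]
  for (s in c(2, 8, 16)) {
    nz <- which(abs(co[s, ]) > 1e-12)
    expect_true(all(nz <= 200 & nz > 200 - 3 * s - 2))
  }
})

test_that("coefficients are time-covariant away from boundaries", {
  set.seed(3)
  n <- 512
  x <- 140 + 8 * sin(2 * pi * seq_len(n) / 30) + rnorm(n)
  k <- 37
  xs <- c(x[(k + 1):n], x[1:k])  # shift left by k
  a <- coeffs(cwtCoefficients(cleanSig(x), "db2", 3))
  b <- coeffs(cwtCoefficients(cleanSig(xs), "db2", 3))
  guard <- 3 * 8 + 2  # one wavelet support at the largest scale
  interior <- (guard + 1):(n - k - guard)
  expect_equal(b[, interior], a[, interior + k], tolerance = 1e-9)
})

test_that("higher-frequency sinusoids peak at smaller scales", {
  n <- 2048
  bestScale <- vapply(c(16, 32, 64, 128), function(period) {
    x <- 140 + 10 * sin(2 * pi * seq_len(n) / period)
    co <- coeffs(cwtCoefficients(cleanSig(x), "db2", 6))
    interior <- 300:(n - 300)
    which.max(apply(abs(co[, interior]), 1, max))
  }, 0L)
  expect_true(all(diff(bestScale) > 0))
})

test_that("rendered images have the contracted shape, range and degeneracies", {
  set.seed(4)
  x <- 140 + cumsum(rnorm(600))
  sc <- cwtCoefficients(cleanSig(x), "db2", 4)
  for (res in c(16, 28, 36, 64)) {
    img <- renderImage(sc, res)
    expect_identical(dim(pixels(img)), as.integer(c(res, res, 3)))
    expect_true(all(pixels(img) >= 0 & pixels(img) <= 1))
  }
  # all-zero scalogram renders as a uniform mid-colormap image
  zsc <- cwtCoefficients(rawRec(x * 0), "db2", 4)
  img <- pixels(renderImage(zsc, 16))
  expect_true(all(abs(img - rep(img[1, 1, ], each = 256)) < 1e-12))
  # log scaling stays in range too
  img <- renderImage(sc, 32, scaling = "log")
  expect_true(all(pixels(img) >= 0 & pixels(img) <= 1))
})

test_that("low-resolution rendering upsampled matches high-resolution rendering", {
  # a smooth band-limited trace: resize consistency of the triangle kernel
  # is only meaningful below the output Nyquist rate
  t <- seq_len(2048)
  x <- 140 + 15 * sin(2 * pi * t / 500) + 5 * sin(2 * pi * t / 150)
  sc <- cwtCoefficients(cleanSig(x), "db2", 4)
  i28 <- pixels(renderImage(sc, 28))
  i64 <- pixels(renderImage(sc, 64))
  ss <- vapply(1:3, function(ch) {
    up <- ctgcnn:::.resizeMatrix(i28[, , ch], 64, 64)
    ssimIndex(up, i64[, , ch])
  }, 0)
  expect_gt(mean(ss), 0.8)
})

test_that("dataset cardinality and labels are conserved", {
  sigs <- lapply(1:3, function(i) {
    cleanSig(140 + sin(seq_len(256) / (3 + i)) * 10,
             label = if (i == 1) "pathological" else "normal",
             id = sprintf("s%d", i))
  })
  set <- buildImageDataset(sigs, families = c("db2", "sym2"),
                           exponents = c(4, 5), resolution = 16)
  expect_length(imageLabels(set), 3 * 2 * 2)
  expect_identical(sum(imageLabels(set) == "pathological"), 4L)
  expect_identical(dim(imageArray(set)), c(16L, 16L, 3L, 12L))
  # unit case: one record, one family, one exponent
  one <- buildImageDataset(sigs[1], families = "db2", exponents = 4,
                           resolution = 16)
  expect_length(imageLabels(one), 1)
  expect_identical(imageLabels(one), "pathological")
  # unlabelled records are skipped with a warning
  sigs[[2]]@label <- "unknown"
  expect_warning(set2 <- buildImageDataset(sigs, families = "db2",
                                           exponents = 4, resolution = 16),
                 "skipping")
  expect_length(imageLabels(set2), 2)
})
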