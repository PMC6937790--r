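# Shared fixture builders; everything is generated in code at test time.

cleanSig <- function(x, fs = 4, label = "normal", id = "fix") {
  new("CleanSignal", sourceId = id, samples = x, fs = fs,
      editMask = rep("untouched", length(x)), label = label,
      range = c(50, 200))
}

rawRec <- function(x, fs = 4, label = "normal", id = "fix", ph = NA_real_) {
  FHRRecord(id, x, fs = fs, ph = ph, label = label)
}

# a small random image set with the requested class counts
randomImageSet <- function(nNormal, nPath, res = 16, seed = 1) {
  set.seed(seed)
  n <- nNormal + nPath
  imgs <- array(runif(res * res * 3 * n), c(res, res, 3, n))
  labels <- c(rep("normal", nNormal), rep("pathological", nPath))
  meta <- data.frame(sourceId = sprintf("r%03d", seq_len(n)),
                     family = "db2", exponent = 4, stringsAsFactors = FALSE)
  new("TFImageSet", images = imgs, labels = labels, meta = meta)
}

toyCnnConfig <- function(...) {
  cnnConfig(inputResolution = 6, numChannels = 1, kernelSize = 3,
            numFilters = 2, fcWidth = 4, miniBatch = 2, maxEpochs = 2, ...)
}

# all permutations of a vector (n! rows)
allPerms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- allPerms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# brute-force direct summation of the CWT definition using the same
# discretised kernels as the implementation under test
cwtOracle <- function(x, fs, family, exponent) {
  w <- motherWavelet(family, 4096)
  sup <- max(w$x)
  dx <- w$x[2] - w$x[1]
  Psi <- c(0, cumsum(w$psi[-1] + w$psi[-length(w$psi)]) / 2 * dx)
  n <- length(x)
  dt <- 1 / fs
  scales <- seq_len(2^exponent)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    m <- 0:ceiling(sup * s + 0.5)
    hi <- approx(w$x, Psi, xout = pmin(pmax((m + 0.5) / s, 0), sup), rule = 2)$y
    lo <- approx(w$x, Psi, xout = pmin(pmax((m - 0.5) / s, 0), sup), rule = 2)$y
    k <- s * (hi - lo) / sqrt(s) * dt
    for (tau in seq_len(n)) {
      acc <- 0
      for (j in seq_along(m)) {
        t <- tau + m[j]
        if (t <= n) acc <- acc + x[t] * k[j]
      }
      out[si, tau] <- acc
    }
  }
  out
}

# mean structural similarity between two equally sized grayscale matrices
ssimIndex <- function(a, b) {
  c1 <- (0.01)^2; c2 <- (0.03)^2
  mu1 <- mean(a); mu2 <- mean(b)
  v1 <- var(as.vector(a)); v2 <- var(as.vector(b))
  cv <- cov(as.vector(a), as.vector(b))
  ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}
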