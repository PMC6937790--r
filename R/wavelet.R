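setAs("CleanSignal", "FHRRecord", function(from) {
  new("FHRRecord", recordId = from@sourceId, samples = from@samples,
      fs = from@fs, ph = NA_real_, label = from@label,
      metadata = list(editMask = from@editMask))
})

# Orthonormal scaling filters (sum h = sqrt(2)).  At order 2 the symlet
# construction coincides with the Daubechies filter, so "sym2" and "db2"
# share coefficients; both names are kept because datasets are enriched by
# enumerating the two families.
.waveletFilter <- function(family = c("db2", "sym2")) {
  family <- match.arg(family)
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)  # quadrature mirror: g_k = (-1)^k h_{N-1-k}
  list(h = h, g = g, support = c(0, length(h) - 1))
}

# Exact values of the scaling function on the dyadic grid 2^-level via the
# two-scale relation phi(x) = sqrt(2) sum_k h_k phi(2x - k), seeded with the
# integer values from the eigenvector of the transfer matrix.
.scalingOnDyadic <- function(h, level) {
  N <- length(h)
  intSupport <- 1:(N - 2)
  M <- outer(intSupport, intSupport,
             function(i, j) ifelse(2 * i - j >= 0 & 2 * i - j <= N - 1,
                                   sqrt(2) * h[2 * i - j + 1], 0))
  ev <- eigen(M)
  k <- which.min(abs(ev$values - 1))
  phiInt <- Re(ev$vectors[, k])
  phiInt <- phiInt / sum(phiInt)  # partition of unity at the integers
  phi <- numeric((N - 1) + 1)     # grid spacing 1 at level 0
  phi[intSupport + 1] <- phiInt
  for (lev in seq_len(level)) {
    nOld <- length(phi)
    xNew <- seq(0, N - 1, by = 2^-lev)
    phiNew <- numeric(length(xNew))
    for (k2 in 0:(N - 1)) {
      # phi(2x - k) on the previous grid
      pos <- 2 * xNew - k2
      onGrid <- pos >= 0 & pos <= N - 1
      idx <- round(pos[onGrid] * 2^(lev - 1)) + 1
      idx <- pmin(pmax(idx, 1), nOld)
      phiNew[onGrid] <- phiNew[onGrid] + sqrt(2) * h[k2 + 1] * phi[idx]
    }
    phi <- phiNew
  }
  phi
}

#' Sample a mother wavelet
#'
#' Returns the order-2 Daubechies / symlet mother wavelet sampled on a
#' dyadic grid over its support `[0, 3]`, computed exactly from the
#' two-scale refinement relation (integer values from the transfer-matrix
#' eigenvector, then dyadic subdivision). The discretisation satisfies the
#' admissibility condition: the Riemann sum of the wavelet over its support
#' vanishes.
#'
#' @param family `"db2"` or `"sym2"` (identical at order 2).
#' @param resolution minimum number of sample points over the support
#'   (at least 256 for a faithful discretisation).
#' @return A list with `x` (sample positions) and `psi` (wavelet values).
#' @examples
#' w <- motherWavelet("db2", 1024)
#' abs(sum(w$psi) * diff(w$x[1:2]))  # admissibility, ~0
#' @export
motherWavelet <- function(family = c("db2", "sym2"), resolution = 1024) {
  family <- match.arg(family)
  if (resolution < 8) stop("motherWavelet: resolution too small")
  flt <- .waveletFilter(family)
  N <- length(flt$h)
  sup <- N - 1
  level <- max(1, ceiling(log2((resolution - 1) / sup)))
  # psi on grid 2^-level needs phi on grid 2^-(level+1) is not required:
  # psi(x) = sqrt(2) sum_k g_k phi(2x - k), with 2x on the 2^-(level) grid
  phi <- .scalingOnDyadic(flt$h, level)
  x <- seq(0, sup, by = 2^-level)
  psi <- numeric(length(x))
  for (k in 0:(N - 1)) {
    pos <- 2 * x - k
    onGrid <- pos >= 0 & pos <= sup
    idx <- round(pos[onGrid] * 2^level) + 1
    idx <- pmin(pmax(idx, 1), length(phi))
    psi[onGrid] <- psi[onGrid] + sqrt(2) * flt$g[k + 1] * phi[idx]
  }
  list(x = x, psi = psi, family = family)
}

.kernelCache <- new.env(parent = emptyenv())

# Cell-averaged kernel sampling via the antiderivative Psi of psi: point
# sampling at small scales breaks the zero-sum admissibility and leaks the
# large DC baseline of heart-rate traces into the finest scale rows.
# k[m] = (1/sqrt(s)) * s * (Psi((m+.5)/s) - Psi((m-.5)/s)) * dt, which sums
# to zero exactly at every scale because Psi(0) = Psi(support) = 0.
# Kernels depend only on (family, exponent, fs, resolution) and are cached.
.cwtKernels <- function(family, exponent, fs, waveletResolution) {
  key <- paste(family, exponent, fs, waveletResolution, sep = "|")
  cached <- .kernelCache[[key]]
  if (!is.null(cached)) return(cached)
  w <- motherWavelet(family, waveletResolution)
  sup <- max(w$x)
  dx <- w$x[2] - w$x[1]
  dt <- 1 / fs
  Psi <- c(0, cumsum(w$psi[-1] + w$psi[-length(w$psi)]) / 2 * dx)
  kernels <- lapply(seq_len(2^exponent), function(s) {
    m <- 0:ceiling(sup * s + 0.5)
    hi <- approx(w$x, Psi, xout = pmin(pmax((m + 0.5) / s, 0), sup), rule = 2)$y
    lo <- approx(w$x, Psi, xout = pmin(pmax((m - 0.5) / s, 0), sup), rule = 2)$y
    s * (hi - lo) / sqrt(s) * dt
  })
  .kernelCache[[key]] <- kernels
  kernels
}

#' Continuous wavelet transform of a cleaned trace
#'
#' Computes `coef[s, tau] = sum_t f(t) (1/sqrt(s)) psi((t - tau)/s) dt` for
#' every integer scale `s = 1..2^exponent` and every translation `tau`
#' (one per signal sample), with zero extension outside the signal. The
#' scale axis is the dyadic ladder implied by the scale exponent: a single
#' scale cannot produce a two-dimensional image, so exponent J spans the
#' integer scales up to `2^J`.
#'
#' @param signal a [CleanSignal-class] (or any object with `samples()` and
#'   `sampleRate()`).
#' @param family mother wavelet family, `"db2"` or `"sym2"`.
#' @param exponent dyadic scale exponent, conventionally 4, 5 or 6.
#' @param waveletResolution grid resolution used to sample the mother
#'   wavelet before scale-dependent resampling.
#' @return A [Scalogram-class].
#' @export
cwtCoefficients <- function(signal, family = c("db2", "sym2"), exponent = 4,
                            waveletResolution = 4096) {
  family <- match.arg(family)
  if (exponent < 1) stop("cwtCoefficients: scale exponent must be >= 1 (scale 0 is undefined)")
  x <- samples(signal)
  if (length(x) == 0) stop("cwtCoefficients: empty signal")
  fs <- sampleRate(signal)
  dt <- 1 / fs
  scalesVec <- seq_len(2^exponent)
  kernels <- .cwtKernels(family, exponent, fs, waveletResolution)
  co <- cwt_correlate(as.numeric(x), kernels)
  new("Scalogram", coeffs = co, scales = as.numeric(scalesVec), dt = dt,
      family = family, exponent = exponent,
      sourceId = recordId(signal))
}
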