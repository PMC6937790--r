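#' Synthetic cardiotocography simulation settings
#'
#' The simulator is a test harness, not a physiological model: it produces
#' 4 Hz heart-rate traces with the features the pipeline consumes -- a
#' class-dependent baseline, band-limited short-term variability,
#' Poisson-arriving accelerations and decelerations -- plus the three
#' artifact kinds the cleaning rules target (zeroed gaps, spikes above
#' 25 bpm, values outside 50-200 bpm). The pathological class mirrors the
#' clinical markers of hypoxic distress: a lower baseline, reduced
#' short-term variability and deeper, more frequent decelerations; this
#' also makes the two classes separable by construction.
#'
#' @param durationMin trace duration in minutes.
#' @param fs sampling rate (Hz).
#' @param baselineNormal,baselinePathological baseline ranges (bpm).
#' @param variabilityNormal,variabilityPathological peak-to-peak short-term
#'   variability ranges (bpm).
#' @param arCoefNormal,arCoefPathological autoregressive coefficient of the
#'   band-limited variability noise. The pathological value is closer to 1,
#'   i.e. the trace is smoother: loss of short-term variability is the
#'   classical hypoxia marker, and unlike the raw amplitude it survives the
#'   per-image normalisation of the rendered scalograms, which is what
#'   makes the two classes separable by construction.
#' @param accelRateNormal,accelRatePathological accelerations per hour.
#' @param decelRateNormal,decelRatePathological decelerations per hour.
#' @param decelDepthNormal,decelDepthPathological deceleration depth ranges
#'   (bpm below baseline).
#' @param missingRate,spikeRate,extremeRate artifact intensities per
#'   minute: zeroed gaps, >25 bpm spikes, out-of-range values.
#' @return A plain list of settings consumed by [simulateRecord()],
#'   [injectArtifacts()] and [makeBenchmarkSet()].
#' @export
simConfig <- function(durationMin = 30, fs = 4,
                      baselineNormal = c(120, 160),
                      baselinePathological = c(100, 130),
                      variabilityNormal = c(5, 15),
                      variabilityPathological = c(1, 5),
                      arCoefNormal = 0.8, arCoefPathological = 0.97,
                      accelRateNormal = 10, accelRatePathological = 2,
                      decelRateNormal = 2, decelRatePathological = 10,
                      decelDepthNormal = c(15, 30),
                      decelDepthPathological = c(30, 60),
                      missingRate = 0.25, spikeRate = 0.5,
                      extremeRate = 0.2) {
  stopifnot(durationMin > 0, fs > 0,
            diff(baselineNormal) >= 0, diff(baselinePathological) >= 0,
            diff(variabilityNormal) >= 0, diff(variabilityPathological) >= 0,
            missingRate >= 0, spikeRate >= 0, extremeRate >= 0)
  list(durationMin = durationMin, fs = fs,
       baselineNormal = baselineNormal,
       baselinePathological = baselinePathological,
       variabilityNormal = variabilityNormal,
       variabilityPathological = variabilityPathological,
       arCoefNormal = arCoefNormal,
       arCoefPathological = arCoefPathological,
       accelRateNormal = accelRateNormal,
       accelRatePathological = accelRatePathological,
       decelRateNormal = decelRateNormal,
       decelRatePathological = decelRatePathological,
       decelDepthNormal = decelDepthNormal,
       decelDepthPathological = decelDepthPathological,
       missingRate = missingRate, spikeRate = spikeRate,
       extremeRate = extremeRate)
}

.gaussBump <- function(n, center, widthSamples, amp) {
  t <- seq_len(n)
  amp * exp(-0.5 * ((t - center) / (widthSamples / 4))^2)
}

#' Simulate a clean fetal heart-rate record
#'
#' Clean trace = baseline (constant plus a slow sinusoidal drift) +
#' AR(1)-filtered Gaussian variability with a class-dependent bandwidth,
#' scaled to the class's peak-to-peak band, + Gaussian-bump accelerations
#' (+10..+25 bpm, 15-60 s) and
#' decelerations (class-dependent depth, 15-60 s) arriving as Poisson
#' events. The trace is softly floored at 52 bpm so deep pathological
#' decelerations stay inside the physiological band. Fully determined by
#' `seed`.
#'
#' @param cfg a [simConfig()].
#' @param class `"normal"` or `"pathological"`.
#' @param seed integer RNG seed.
#' @param recordId identifier for the simulated record.
#' @return List with `record` (an [FHRRecord-class] labelled `class`) and
#'   `truth` (list with `cleanSamples` and an all-clean `artifactMask`).
#' @examples
#' sim <- simulateRecord(simConfig(durationMin = 20), "normal", seed = 7)
#' length(samples(sim$record))  # 4800
#' @export
simulateRecord <- function(cfg = simConfig(), class = c("normal", "pathological"),
                           seed = 1, recordId = sprintf("sim%05d", seed)) {
  class <- match.arg(class)
  set.seed(seed)
  n <- round(cfg$durationMin * 60 * cfg$fs)
  pick <- function(nm) cfg[[paste0(nm, if (class == "normal") "Normal" else "Pathological")]]
  b0 <- runif(1, pick("baseline")[1], pick("baseline")[2])
  drift <- runif(1, 1, 4) * sin(2 * pi * seq_len(n) / (cfg$fs * 60 * runif(1, 8, 15)) +
                                runif(1, 0, 2 * pi))
  vAmp <- runif(1, pick("variability")[1], pick("variability")[2])
  noise <- as.numeric(stats::filter(rnorm(n), pick("arCoef"),
                                    method = "recursive"))
  noise <- noise / sd(noise) * (vAmp / 4)  # peak-to-peak roughly vAmp
  x <- b0 + drift + noise
  hours <- cfg$durationMin / 60
  nAcc <- rpois(1, pick("accelRate") * hours)
  for (i in seq_len(nAcc)) {
    dur <- runif(1, 15, 60) * cfg$fs
    x <- x + .gaussBump(n, runif(1, 1, n), dur, runif(1, 10, 25))
  }
  nDec <- rpois(1, pick("decelRate") * hours)
  dd <- pick("decelDepth")
  for (i in seq_len(nDec)) {
    dur <- runif(1, 15, 60) * cfg$fs
    x <- x - .gaussBump(n, runif(1, 1, n), dur, runif(1, dd[1], dd[2]))
  }
  x <- pmax(x, 52)
  rec <- FHRRecord(recordId, x, fs = cfg$fs, label = class)
  list(record = rec,
       truth = list(cleanSamples = x, artifactMask = rep("clean", n),
                    class = class))
}

#' Inject artifacts with a known ground-truth mask
#'
#' Adds the three noise kinds the cleaning stages target, at seeded random
#' positions: zero runs (a mix of short, interpolatable gaps of 2-12 s and
#' long, removable gaps of 16-25 s), isolated spikes offset by more than
#' 25 bpm, and non-physiological extreme samples (below 50 or above
#' 200 bpm). The returned mask flags every modified sample.
#'
#' @param record a clean [FHRRecord-class].
#' @param cfg a [simConfig()] supplying the per-minute artifact rates.
#' @param seed integer RNG seed.
#' @param longGapShare share of gaps drawn from the long (>15 s) regime.
#' @return List with `record` (artifacts injected) and `truth` (clean
#'   samples plus a per-sample mask in
#'   `{"clean", "zeroed", "spiked", "extreme"}`).
#' @export
injectArtifacts <- function(record, cfg = simConfig(), seed = 1,
                            longGapShare = 0.3) {
  set.seed(seed)
  clean <- record@samples
  x <- clean
  n <- length(x)
  fs <- record@fs
  mask <- rep("clean", n)
  minutes <- n / fs / 60
  margin <- round(5 * fs)  # keep artifacts away from the very edges
  nGap <- rpois(1, cfg$missingRate * minutes)
  nSpike <- rpois(1, cfg$spikeRate * minutes)
  nExtreme <- rpois(1, cfg$extremeRate * minutes)
  for (i in seq_len(nGap)) {
    long <- runif(1) < longGapShare
    durS <- if (long) runif(1, 16, 25) else runif(1, 2, 12)
    len <- round(durS * fs)
    s <- sample.int(max(1, n - len - 2 * margin), 1) + margin
    x[s:(s + len - 1)] <- 0
    mask[s:(s + len - 1)] <- "zeroed"
  }
  for (i in seq_len(nSpike)) {
    p <- sample.int(n - 2 * margin, 1) + margin
    if (mask[p] != "clean") next
    x[p] <- x[p] + sample(c(-1, 1), 1) * runif(1, 35, 60)
    mask[p] <- "spiked"
  }
  for (i in seq_len(nExtreme)) {
    p <- sample.int(n - 2 * margin, 1) + margin
    if (mask[p] != "clean") next
    x[p] <- if (runif(1) < 0.5) runif(1, 205, 230) else runif(1, 25, 45)
    mask[p] <- "extreme"
  }
  if (mean(mask != "clean") > 0.5)
    stop("injectArtifacts: artifact rates corrupt more than half the record")
  record@samples <- x
  list(record = record,
       truth = list(cleanSamples = clean, artifactMask = mask))
}

#' Simulate, clean and render a separable two-class benchmark
#'
#' Simulates `nPerClass` records per class, injects artifacts, runs the
#' full cleaning pipeline and renders one scalogram image per record. The
#' two classes are separable by construction (distinct variability and
#' deceleration regimes), giving the classifier a sanity benchmark with
#' known structure.
#'
#' @param nPerClass records per class.
#' @param cfg a [simConfig()]; its duration should exceed the analysis
#'   segment so long-gap removal leaves enough signal.
#' @param resolution image side length (pixels).
#' @param family,exponent wavelet settings for the rendered images.
#' @param scaling magnitude scaling for [renderImage()]; the benchmark
#'   defaults to `"log"` so that both the variability texture and the
#'   deceleration transients separating the classes stay visible.
#' @param seed integer RNG seed; record seeds are derived from it.
#' @param withArtifacts inject artifacts before cleaning.
#' @param prep a [preprocessConfig()].
#' @return A [TFImageSet-class] with `2 * nPerClass` labelled images.
#' @export
makeBenchmarkSet <- function(nPerClass = 200, cfg = simConfig(durationMin = 24),
                             resolution = 64, family = "db2", exponent = 5,
                             scaling = "log", seed = 1, withArtifacts = TRUE,
                             prep = preprocessConfig()) {
  stopifnot(nPerClass >= 1)
  signals <- vector("list", 2 * nPerClass)
  i <- 0L
  for (class in c("normal", "pathological")) {
    for (r in seq_len(nPerClass)) {
      i <- i + 1L
      recSeed <- seed * 100000 + i
      sim <- simulateRecord(cfg, class, seed = recSeed,
                            recordId = sprintf("bench_%s_%03d", class, r))
      rec <- sim$record
      if (withArtifacts)
        rec <- injectArtifacts(rec, cfg, seed = recSeed + 50000)$record
      signals[[i]] <- preprocessRecord(rec, prep)
    }
  }
  buildImageDataset(signals, families = family, exponents = exponent,
                    resolution = resolution, scaling = scaling)
}
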