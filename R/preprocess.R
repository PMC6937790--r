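#' Preprocessing configuration
#'
#' Thresholds of the three-stage artifact-removal algorithm. Defaults follow
#' the established cardiotocography cleaning rules: zero-valued gaps of at
#' most 15 s are spline-interpolated while longer gaps are removed outright;
#' an adjacent-sample difference above 25 bpm starts a spike bridge that
#' ends at the first "stable section" (five adjacent samples whose
#' successive differences are all below 10 bpm); values outside the
#' physiological band 50-200 bpm are restored by cubic spline interpolation;
#' the final analysis segment is 20 minutes long.
#'
#' @param maxGapS longest zero gap (seconds) that is interpolated rather
#'   than removed.
#' @param spikeDiffBpm adjacent difference (bpm) that triggers a spike
#'   bridge (strict inequality).
#' @param stableLen number of adjacent samples forming a stable section.
#' @param stableDiffBpm successive-difference bound (bpm) inside a stable
#'   section (strict inequality).
#' @param minBpm,maxBpm physiological heart-rate band (bpm).
#' @param segmentMinutes duration of the extracted analysis segment.
#' @return A `PreprocessConfig` object.
#' @export
preprocessConfig <- function(maxGapS = 15, spikeDiffBpm = 25, stableLen = 5,
                             stableDiffBpm = 10, minBpm = 50, maxBpm = 200,
                             segmentMinutes = 20) {
  new("PreprocessConfig", maxGapS = maxGapS, spikeDiffBpm = spikeDiffBpm,
      stableLen = stableLen, stableDiffBpm = stableDiffBpm, minBpm = minBpm,
      maxBpm = maxBpm, segmentMinutes = segmentMinutes)
}

#' @rdname preprocessConfig
#' @export
setClass("PreprocessConfig",
  slots = c(maxGapS = "numeric", spikeDiffBpm = "numeric",
            stableLen = "numeric", stableDiffBpm = "numeric",
            minBpm = "numeric", maxBpm = "numeric",
            segmentMinutes = "numeric"),
  validity = function(object) {
    vals <- c(object@maxGapS, object@spikeDiffBpm, object@stableDiffBpm,
              object@minBpm, object@maxBpm, object@segmentMinutes)
    if (any(vals <= 0)) return("all thresholds must be positive")
    if (object@minBpm >= object@maxBpm) return("minBpm must be < maxBpm")
    if (object@stableLen < 2) return("stableLen must be >= 2")
    TRUE
  })

.getMask <- function(record) {
  record@metadata$editMask %||% rep("untouched", length(record@samples))
}

.setMask <- function(record, mask) {
  record@metadata$editMask <- mask
  record
}

#' Fill or remove zero-valued signal-loss gaps
#'
#' A gap is a maximal run of samples equal to 0 (transducer signal loss).
#' Gaps no longer than `maxGapS` seconds are replaced by a monotone cubic
#' Hermite spline anchored on short averages of up to eight valid samples
#' per flank (averaging keeps flank noise from being amplified across the
#' gap, and the monotone spline cannot bow outside the flank range); longer
#' gaps, and gaps touching a signal boundary (which lack one flank), are
#' removed so the signal shortens. The first retained sample after a
#' removal is flagged `"removed-adjacent"` in the edit mask.
#'
#' @param record an [FHRRecord-class]; its running edit mask is kept in
#'   `metadata$editMask`.
#' @param cfg a [preprocessConfig()].
#' @return The record with gaps resolved.
#' @export
fillGaps <- function(record, cfg = preprocessConfig()) {
  x <- record@samples
  n <- length(x)
  if (n == 0 || all(x == 0)) stop("fillGaps: signal is empty or all zero")
  mask <- .getMask(record)
  zero <- x == 0
  if (!any(zero)) return(.setMask(record, mask))
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gapRuns <- which(r$values)
  maxGapSamples <- cfg@maxGapS * record@fs
  keep <- rep(TRUE, n)
  removedBefore <- logical(n)  # marks the first kept sample after a removal
  xnew <- x
  for (g in gapRuns) {
    s <- starts[g]; e <- ends[g]
    len <- e - s + 1
    boundary <- s == 1 || e == n
    if (len > maxGapSamples || boundary) {
      keep[s:e] <- FALSE
      if (e < n) removedBefore[e + 1] <- TRUE
    } else {
      # spline anchored on short flank averages (up to two 4-sample chunks
      # per side): anchoring on raw samples would let the natural cubic
      # amplify flank noise into tens of bpm across a long gap
      idxL <- seq.int(max(1, s - 8), s - 1)
      idxL <- idxL[x[idxL] != 0]
      idxR <- seq.int(e + 1, min(n, e + 8))
      idxR <- idxR[x[idxR] != 0]
      chunk <- function(ix, fromEnd) {
        if (length(ix) > 4) {
          split(ix, rep(1:2, times = if (fromEnd)
            c(length(ix) - 4, 4) else c(4, length(ix) - 4)))
        } else list(ix)
      }
      anchors <- c(chunk(idxL, TRUE), chunk(idxR, FALSE))
      pos <- vapply(anchors, mean, 0)
      val <- vapply(anchors, function(ix) mean(x[ix]), 0)
      # monotone cubic Hermite: an unconstrained cubic can bow far outside
      # the flank range across a 40+ sample gap when flank slopes disagree
      sf <- splinefun(pos, val, method = "monoH.FC")
      xnew[s:e] <- sf(s:e)
      mask[s:e] <- "interpolated"
    }
  }
  mask[removedBefore] <- "removed-adjacent"
  record@samples <- xnew[keep]
  .setMask(record, mask[keep])
}

.isStableStart <- function(x, j, len, bound) {
  all(abs(diff(x[j:(j + len - 1)])) < bound)
}

#' Bridge artifactual spikes to the next stable section
#'
#' Scanning left to right, whenever the difference between two adjacent
#' samples exceeds `spikeDiffBpm`, the samples from just after the pre-spike
#' sample up to (but excluding) the first sample of the next stable section
#' are replaced by linear interpolation between those two preserved
#' endpoints; the scan resumes at the stable-section start. If no stable
#' section exists after a spike, the unstable tail is trimmed (bridging to
#' the end of the signal is not allowed) and reported via a message.
#'
#' @inheritParams fillGaps
#' @return The record with spikes bridged.
#' @export
bridgeSpikes <- function(record, cfg = preprocessConfig()) {
  x <- record@samples
  mask <- .getMask(record)
  n <- length(x)
  i <- 1L
  trimAt <- NA_integer_
  lastStart <- n - cfg@stableLen + 1
  while (i < n) {
    if (abs(x[i + 1] - x[i]) > cfg@spikeDiffBpm) {
      j <- i + 1L
      found <- FALSE
      while (j <= lastStart) {
        if (.isStableStart(x, j, cfg@stableLen, cfg@stableDiffBpm)) {
          found <- TRUE
          break
        }
        j <- j + 1L
      }
      if (!found) {
        trimAt <- i + 1L
        break
      }
      if (j > i + 1L) {
        ramp <- seq(x[i], x[j], length.out = j - i + 1)
        interior <- (i + 1L):(j - 1L)
        x[interior] <- ramp[-c(1, length(ramp))]
        mask[interior] <- "interpolated"
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!is.na(trimAt)) {
    .msg("record %s: no stable section after sample %d; trimming %d trailing samples",
         record@recordId, trimAt - 1L, n - trimAt + 1L)
    x <- x[seq_len(trimAt - 1L)]
    mask <- mask[seq_len(trimAt - 1L)]
  }
  record@samples <- x
  .setMask(record, mask)
}

#' Restore non-physiological extreme values
#'
#' Samples outside the physiological band (`< minBpm` or `> maxBpm`) are
#' replaced by a natural cubic spline fitted through the in-range samples
#' (then limited to the band, since an unconstrained spline can overshoot
#' near steep edits). Records with more than half their samples out of range
#' are rejected as unusable.
#'
#' @inheritParams fillGaps
#' @return A [CleanSignal-class] satisfying the no-zero, in-range
#'   invariants.
#' @export
replaceExtremes <- function(record, cfg = preprocessConfig()) {
  x <- record@samples
  mask <- .getMask(record)
  out <- x < cfg@minBpm | x > cfg@maxBpm
  if (mean(out) > 0.5)
    stop(sprintf("replaceExtremes: record %s has %.0f%% of samples out of range",
                 record@recordId, 100 * mean(out)))
  if (any(out)) {
    good <- which(!out)
    sf <- splinefun(good, x[good], method = "natural")
    x[out] <- sf(which(out))
    x <- pmin(pmax(x, cfg@minBpm), cfg@maxBpm)
    mask[out] <- "interpolated"
  }
  new("CleanSignal", sourceId = record@recordId, samples = x,
      fs = record@fs, editMask = mask, label = record@label,
      range = c(cfg@minBpm, cfg@maxBpm))
}

#' Extract the fixed-duration analysis segment
#'
#' Returns the final `segmentMinutes` of the cleaned signal (4800 samples
#' for 20 min at 4 Hz) -- the portion closest to delivery, which is the
#' standard analysis window in intrapartum monitoring. `position = "first"`
#' selects the initial segment instead.
#'
#' @param signal a [CleanSignal-class].
#' @param cfg a [preprocessConfig()].
#' @param position `"last"` (default) or `"first"`.
#' @return A [CleanSignal-class] of exactly the configured duration; an
#'   error if the signal is shorter.
#' @export
extractSegment <- function(signal, cfg = preprocessConfig(),
                           position = c("last", "first")) {
  position <- match.arg(position)
  need <- round(cfg@segmentMinutes * 60 * signal@fs)
  n <- length(signal@samples)
  if (n < need)
    stop(sprintf("extractSegment: record %s has %.1f min < %g min",
                 signal@sourceId, n / signal@fs / 60, cfg@segmentMinutes))
  idx <- if (position == "last") (n - need + 1):n else 1:need
  signal@samples <- signal@samples[idx]
  signal@editMask <- signal@editMask[idx]
  signal
}

#' Run the full artifact-removal pipeline on a record
#'
#' Stage order is fixed: zero-gap handling, then spike bridging, then
#' extreme-value restoration, then (optionally) extraction of the final
#' fixed-duration segment. The pipeline is idempotent: a signal violating no
#' rule passes through bit-identically.
#'
#' @inheritParams fillGaps
#' @param segment if `TRUE`, extract the analysis segment at the end.
#' @param position segment position, see [extractSegment()].
#' @return A [CleanSignal-class].
#' @examples
#' rec <- simulateRecord(simConfig(durationMin = 25), "normal", seed = 1)$record
#' cs <- preprocessRecord(rec)
#' range(samples(cs))
#' @export
preprocessRecord <- function(record, cfg = preprocessConfig(),
                             segment = TRUE, position = "last") {
  cleaned <- replaceExtremes(bridgeSpikes(fillGaps(record, cfg), cfg), cfg)
  if (segment) cleaned <- extractSegment(cleaned, cfg, position)
  cleaned
}
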