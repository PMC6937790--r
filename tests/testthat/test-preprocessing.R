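cfg <- preprocessConfig()

test_that("short zero gaps are interpolated, long and boundary gaps removed", {
  base <- 140 + sin(seq_len(2000) / 40) * 5
  # 10 s gap (40 samples) -> interpolated, length unchanged, no zeros
  x <- base; x[501:540] <- 0
  out <- fillGaps(rawRec(x), cfg)
  expect_length(samples(out), 2000)
  expect_false(any(samples(out) == 0))
  expect_true(all(out@metadata$editMask[501:540] == "interpolated"))
  expect_lt(max(abs(samples(out)[501:540] - base[501:540])), 1)
  # 20 s gap (80 samples) -> removed, length shrinks by 80
  x <- base; x[301:380] <- 0
  out <- fillGaps(rawRec(x), cfg)
  expect_length(samples(out), 1920)
  expect_identical(out@metadata$editMask[301], "removed-adjacent")
  # exactly 15 s (60 samples) is still interpolated ("no more than 15 s")
  x <- base; x[301:360] <- 0
  expect_length(samples(fillGaps(rawRec(x), cfg)), 2000)
  # boundary gap lacks a flank -> trimmed even though short
  x <- base; x[1:20] <- 0
  expect_length(samples(fillGaps(rawRec(x), cfg)), 1980)
  # identity on a gap-free signal, error on an all-zero one
  expect_identical(samples(fillGaps(rawRec(base), cfg)), base)
  expect_error(fillGaps(rawRec(rep(0, 100)), cfg), "all zero")
})

test_that("spikes are bridged to the first sample of the next stable section", {
  # isolated spike in a constant signal: replaced, adjacent diffs fall under 25
  x <- rep(140, 100); x[50] <- 180
  out <- bridgeSpikes(rawRec(x), cfg)
  expect_lt(max(abs(diff(samples(out)))), 25)
  expect_equal(samples(out)[50], 140)
  expect_identical(out@metadata$editMask[50], "interpolated")
  # step onto a new stable level: stable section starts at the first 172
  # sample, so the bridge has no interior and the step survives
  x <- c(rep(140, 50), rep(172, 50))
  out <- bridgeSpikes(rawRec(x), cfg)
  expect_identical(samples(out), x)
  # spiky excursion of several samples before recovery
  x <- rep(140, 100); x[50:52] <- c(190, 195, 185)
  out <- bridgeSpikes(rawRec(x), cfg)
  expect_lt(max(abs(diff(samples(out)))), 25)
  expect_true(all(samples(out)[50:52] >= 140 - 1e-9 &
                  samples(out)[50:52] <= 140 + 1e-9))
  # no pair above 25 bpm -> unchanged
  x <- 140 + cumsum(runif(200, -4, 4))
  expect_identical(samples(bridgeSpikes(rawRec(x), cfg)), x)
  # unstable tail with no stable section after the spike is trimmed
  x <- c(rep(140, 50), 180, c(120, 180, 120, 180, 120, 180))
  expect_message(out <- bridgeSpikes(rawRec(x), cfg), "trimming")
  expect_length(samples(out), 50)
})

test_that("spike bridging agrees with a brute-force scan oracle", {
  # oracle: independent re-implementation of the published rule
  oracle <- function(x, cfg) {
    stable <- function(j) j + 4 <= length(x) &&
      all(abs(diff(x[j:(j + 4)])) < 10)
    i <- 1
    while (i < length(x)) {
      if (abs(x[i + 1] - x[i]) > 25) {
        j <- i + 1
        while (j <= length(x) - 4 && !stable(j)) j <- j + 1
        if (j > length(x) - 4) return(x[1:i])
        if (j > i + 1)
          x[(i + 1):(j - 1)] <- x[i] + (x[j] - x[i]) *
            seq_len(j - i - 1) / (j - i)
        i <- j
      } else i <- i + 1
    }
    x
  }
  set.seed(5)
  for (rep in 1:20) {
    x <- 140 + cumsum(runif(300, -6, 6))
    spikes <- sample(10:290, 3)
    x[spikes] <- x[spikes] + sample(c(-1, 1), 3, TRUE) * runif(3, 30, 80)
    got <- suppressMessages(samples(bridgeSpikes(rawRec(x), cfg)))
    expect_equal(got, oracle(x, cfg), tolerance = 1e-12)
  }
})

test_that("extreme values are restored into the physiological band", {
  base <- 140 + sin(seq_len(500) / 30) * 10
  x <- base; x[200] <- 210
  out <- replaceExtremes(rawRec(x), cfg)
  expect_s4_class(out, "CleanSignal")
  expect_true(all(samples(out) >= 50 & samples(out) <= 200))
  expect_lt(abs(samples(out)[200] - base[200]), 2)
  x <- base; x[100] <- 45
  out <- replaceExtremes(rawRec(x), cfg)
  expect_true(all(samples(out) >= 50))
  # identity when everything is in range
  expect_identical(samples(replaceExtremes(rawRec(base), cfg)), base)
  # quality gate: mostly out-of-range records are rejected
  bad <- c(rep(210, 300), rep(140, 100))
  expect_error(replaceExtremes(rawRec(bad), cfg), "out of range")
})

test_that("segment extraction takes the final fixed-duration window", {
  x <- seq_len(4 * 60 * 40)  # 40 minutes at 4 Hz
  sig <- cleanSig(100 + (x %% 50))
  out <- extractSegment(sig, cfg)
  expect_length(samples(out), 4800)
  expect_identical(samples(out), samples(sig)[(length(x) - 4799):length(x)])
  first <- extractSegment(sig, cfg, position = "first")
  expect_identical(samples(first), samples(sig)[1:4800])
  exact <- cleanSig(rep(140, 4800))
  expect_identical(samples(extractSegment(exact, cfg)), samples(exact))
  short <- cleanSig(rep(140, 3600))  # 15 minutes
  expect_error(extractSegment(short, cfg), "min")
})

test_that("full preprocessing is idempotent and enforces its post-conditions", {
  set.seed(42)
  simCfg <- simConfig(durationMin = 25)
  for (i in 1:10) {
    cl <- if (i %% 2) "normal" else "pathological"
    rec <- simulateRecord(simCfg, cl, seed = 1000 + i)$record
    rec <- injectArtifacts(rec, simCfg, seed = 2000 + i)$record
    cs <- preprocessRecord(rec, cfg)
    expect_false(any(samples(cs) == 0))
    expect_true(all(samples(cs) >= 50 & samples(cs) <= 200))
    expect_length(samples(cs), 4800)
    expect_length(editMask(cs), 4800)
    # applying the pipeline to its own output changes nothing
    cs2 <- preprocessRecord(as(cs, "FHRRecord"), cfg)
    expect_identical(samples(cs2), samples(cs))
  }
})

test_that("edit mask provenance matches the set of modified samples", {
  base <- 140 + sin(seq_len(2000) / 25) * 8
  x <- base
  x[401:420] <- 0          # 5 s gap: interpolated
  x[901] <- 205            # extreme (also a spike; fixed by the spike stage)
  rec <- fillGaps(rawRec(x), cfg)
  rec <- bridgeSpikes(rec, cfg)
  cs <- replaceExtremes(rec, cfg)
  changed <- which(samples(cs) != base)
  flagged <- which(editMask(cs) != "untouched")
  expect_true(all(changed %in% flagged))
  expect_true(all(c(401:420, 901) %in% flagged))
})

test_that("artifact recovery error stays small on smooth simulations", {
  simCfg <- simConfig(durationMin = 25)
  rmseAll <- c()
  for (i in 1:10) {
    sim <- simulateRecord(simCfg, "normal", seed = 300 + i)
    # short gaps only, so lengths stay comparable to the ground truth
    inj <- injectArtifacts(sim$record, simCfg, seed = 400 + i,
                           longGapShare = 0)
    cs <- preprocessRecord(inj$record, cfg, segment = FALSE)
    if (length(samples(cs)) != length(sim$truth$cleanSamples)) next
    edited <- which(editMask(cs) != "untouched")
    if (length(edited) == 0) next
    err <- samples(cs)[edited] - sim$truth$cleanSamples[edited]
    rmseAll <- c(rmseAll, sqrt(mean(err^2)))
  }
  expect_gt(length(rmseAll), 2)
  expect_true(all(rmseAll < 5))
})
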