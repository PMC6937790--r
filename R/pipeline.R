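#' Experiment configuration for the end-to-end pipeline
#'
#' Bundles the per-stage settings. By default the experiment is
#' simulation-backed; set `inputDir`/`dialect` to read records from disk
#' instead. The configured resolution is conventionally one of 16, 28, 36
#' or 64 (the resolution ladder); other values are accepted with a message.
#'
#' @param nPerClass simulated records per class (simulation-backed runs).
#' @param sim a [simConfig()].
#' @param prep a [preprocessConfig()].
#' @param families,exponents wavelet settings.
#' @param resolution image side length in pixels.
#' @param cnn a [cnnConfig()]; its input resolution is aligned with
#'   `resolution`.
#' @param k cross-validation folds.
#' @param grouping `"image"` or `"record"` (see [tenFoldCV()]).
#' @param seed master seed propagated to all stages.
#' @param inputDir optional directory of records to read instead of
#'   simulating.
#' @param dialect record dialect for `inputDir`, `"csv"` or `"wfdb"`.
#' @return A list with class `ExperimentConfig`.
#' @export
experimentConfig <- function(nPerClass = 30, sim = simConfig(durationMin = 24),
                             prep = preprocessConfig(),
                             families = "db2", exponents = 5,
                             resolution = 64, cnn = NULL, k = 10,
                             grouping = "image", seed = 1,
                             inputDir = NULL, dialect = "csv") {
  if (!resolution %in% c(16, 28, 36, 64))
    .msg("resolution %d is outside the conventional ladder 16/28/36/64", resolution)
  if (is.null(cnn)) cnn <- cnnConfig(inputResolution = resolution, seed = seed)
  if (cnn@inputResolution != resolution)
    stop("experimentConfig: cnn input resolution must equal the image resolution")
  structure(list(nPerClass = nPerClass, sim = sim, prep = prep,
                 families = families, exponents = exponents,
                 resolution = resolution, cnn = cnn, k = k,
                 grouping = grouping, seed = seed, inputDir = inputDir,
                 dialect = dialect),
            class = "ExperimentConfig")
}

.ingestRecords <- function(cfg) {
  if (!is.null(cfg$inputDir)) {
    ext <- if (cfg$dialect == "wfdb") "\\.hea$" else "\\.(csv|txt)$"
    files <- list.files(cfg$inputDir, ext, full.names = TRUE)
    if (length(files) == 0) stop("runExperiment: no records in ", cfg$inputDir)
    lapply(files, readRecord, dialect = cfg$dialect)
  } else {
    recs <- vector("list", 2 * cfg$nPerClass)
    i <- 0L
    for (class in c("normal", "pathological")) {
      for (r in seq_len(cfg$nPerClass)) {
        i <- i + 1L
        s <- cfg$seed * 100000 + i
        sim <- simulateRecord(cfg$sim, class, seed = s,
                              recordId = sprintf("exp_%s_%03d", class, r))
        recs[[i]] <- injectArtifacts(sim$record, cfg$sim, seed = s + 50000)$record
      }
    }
    recs
  }
}

#' Run the end-to-end experiment
#'
#' Ingest (or simulate) records, clean them, render the labelled scalogram
#' image dataset, run stratified k-fold cross-validation of the CNN, and
#' return per-fold metrics, their average, and a reproducibility manifest
#' (seed, per-stage record counts and rejection log). Records rejected by
#' the cleaning stages (too short, too corrupted) are logged with the rule
#' that rejected them; counts always satisfy in = out + rejected.
#'
#' @param cfg an [experimentConfig()].
#' @param verbose print stage progress.
#' @return List with `perFold`, `mean` (the five averaged metrics),
#'   and `manifest`.
#' @export
runExperiment <- function(cfg = experimentConfig(), verbose = FALSE) {
  records <- .ingestRecords(cfg)
  nIn <- length(records)
  signals <- list()
  rejections <- data.frame(recordId = character(), rule = character())
  for (rec in records) {
    res <- tryCatch(preprocessRecord(rec, cfg$prep),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rule <- if (grepl("extractSegment", res)) "segment-too-short"
              else if (grepl("replaceExtremes", res)) "quality"
              else "preprocess"
      rejections <- rbind(rejections,
                          data.frame(recordId = recordId(rec), rule = rule))
    } else {
      signals[[length(signals) + 1L]] <- res
    }
  }
  if (verbose) .msg("preprocessed %d/%d records (%d rejected)",
                    length(signals), nIn, nrow(rejections))
  images <- buildImageDataset(signals, families = cfg$families,
                              exponents = cfg$exponents,
                              resolution = cfg$resolution)
  cv <- tenFoldCV(images, cfg$cnn, k = cfg$k, grouping = cfg$grouping,
                  seed = cfg$seed, verbose = verbose)
  manifest <- list(seed = cfg$seed, resolution = cfg$resolution,
                   families = cfg$families, exponents = cfg$exponents,
                   recordsIn = nIn, recordsClean = length(signals),
                   recordsRejected = nrow(rejections),
                   rejections = rejections,
                   nImages = length(imageLabels(images)),
                   labelCounts = as.list(table(imageLabels(images))))
  list(perFold = cv$perFold, mean = cv$mean, manifest = manifest)
}

#' Grid search over CNN hyperparameters
#'
#' Evaluates each (kernel size, filter count) cell with the
#' cross-validation harness on a fixed image set, reporting the six
#' indicator columns (Acc, Se, Sp, QI, AUC and wall-clock training time).
#' A cell whose configuration is invalid (e.g. a kernel that does not tile
#' the pooling grid) is marked failed and the remaining cells still run.
#'
#' @param images a [TFImageSet-class].
#' @param baseCfg the [cnnConfig()] whose other settings are held fixed.
#' @param kernels integer vector of kernel sizes.
#' @param filters integer vector of filter counts.
#' @param k cross-validation folds.
#' @param seed partition seed.
#' @return data.frame with one row per grid cell: `kernel`, `filters`,
#'   `acc`, `se`, `sp`, `qi`, `auc`, `timeSec`, `status`.
#' @export
gridSearch <- function(images, baseCfg = cnnConfig(), kernels = c(3, 5),
                       filters = c(5, 15), k = 10, seed = baseCfg@seed) {
  grid <- expand.grid(kernel = kernels, filters = filters)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- data.frame(kernel = grid$kernel[i], filters = grid$filters[i],
                      acc = NA_real_, se = NA_real_, sp = NA_real_,
                      qi = NA_real_, auc = NA_real_, timeSec = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      cfg <- baseCfg
      cfg@kernelSize <- grid$kernel[i]
      cfg@numFilters <- grid$filters[i]
      validObject(cfg)
      t0 <- proc.time()[3]
      cv <- tenFoldCV(images, cfg, k = k, seed = seed)
      c(cv$mean, timeSec = proc.time()[3] - t0)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      row$status <- paste("failed:", res)
    } else {
      row[c("acc", "se", "sp", "qi", "auc", "timeSec")] <- res
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
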