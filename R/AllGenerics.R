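#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object of one of the package's classes.
#' @return The corresponding component: `samples()` the bpm trace,
#'   `sampleRate()` the Hz, `recordId()` / `sourceIds()` identifiers,
#'   `phValue()` the pH, `recordLabel()` / `imageLabels()` class labels,
#'   `editMask()` the per-sample edit provenance, `coeffs()` and `scales()`
#'   the scalogram content, `pixels()` / `imageArray()` image data,
#'   `trainingHistory()` the per-iteration loss/accuracy table, and
#'   `modelConfig()` the [CNNConfig-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setGeneric("phValue", function(object) standardGeneric("phValue"))
#' @rdname accessors
#' @export
setGeneric("recordLabel", function(object) standardGeneric("recordLabel"))
#' @rdname accessors
#' @export
setGeneric("editMask", function(object) standardGeneric("editMask"))
#' @rdname accessors
#' @export
setGeneric("coeffs", function(object) standardGeneric("coeffs"))
#' @rdname accessors
#' @export
setGeneric("scales", function(object) standardGeneric("scales"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("imageArray", function(object) standardGeneric("imageArray"))
#' @rdname accessors
#' @export
setGeneric("imageLabels", function(object) standardGeneric("imageLabels"))
#' @rdname accessors
#' @export
setGeneric("imageMeta", function(object) standardGeneric("imageMeta"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname accessors
setMethod("samples", "FHRRecord", function(object) object@samples)
#' @rdname accessors
setMethod("samples", "CleanSignal", function(object) object@samples)
#' @rdname accessors
setMethod("sampleRate", "FHRRecord", function(object) object@fs)
#' @rdname accessors
setMethod("sampleRate", "CleanSignal", function(object) object@fs)
#' @rdname accessors
setMethod("recordId", "FHRRecord", function(object) object@recordId)
#' @rdname accessors
setMethod("recordId", "CleanSignal", function(object) object@sourceId)
#' @rdname accessors
setMethod("phValue", "FHRRecord", function(object) object@ph)
#' @rdname accessors
setMethod("recordLabel", "FHRRecord", function(object) object@label)
#' @rdname accessors
setMethod("recordLabel", "CleanSignal", function(object) object@label)
#' @rdname accessors
setMethod("recordLabel", "TFImage", function(object) object@label)
#' @rdname accessors
setMethod("editMask", "CleanSignal", function(object) object@editMask)
#' @rdname accessors
setMethod("coeffs", "Scalogram", function(object) object@coeffs)
#' @rdname accessors
setMethod("scales", "Scalogram", function(object) object@scales)
#' @rdname accessors
setMethod("pixels", "TFImage", function(object) object@pixels)
#' @rdname accessors
setMethod("imageArray", "TFImageSet", function(object) object@images)
#' @rdname accessors
setMethod("imageLabels", "TFImageSet", function(object) object@labels)
#' @rdname accessors
setMethod("imageMeta", "TFImageSet", function(object) object@meta)
#' @rdname accessors
setMethod("trainingHistory", "CNNModel", function(object) object@history)
#' @rdname accessors
setMethod("modelConfig", "CNNModel", function(object) object@config)

setMethod("show", "FHRRecord", function(object) {
  cat(sprintf("FHRRecord '%s': %d samples at %g Hz (%.1f min), pH %s, label %s\n",
              object@recordId, length(object@samples), object@fs,
              length(object@samples) / object@fs / 60,
              ifelse(is.na(object@ph), "n/a", format(object@ph)),
              object@label))
})

setMethod("show", "CleanSignal", function(object) {
  edited <- sum(object@editMask != "untouched")
  cat(sprintf("CleanSignal '%s': %d samples at %g Hz, %d edited, label %s\n",
              object@sourceId, length(object@samples), object@fs,
              edited, object@label))
})

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram '%s': %s, scales 1..%d, %d translations\n",
              object@sourceId, object@family, max(object@scales),
              ncol(object@coeffs)))
})

setMethod("show", "TFImageSet", function(object) {
  d <- dim(object@images)
  tab <- table(object@labels)
  cat(sprintf("TFImageSet: %d images of %dx%dx3 (%s)\n", d[4], d[1], d[2],
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "CNNModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "CNNModel (%s): input %dx%dx%d, %d filters of %dx%d, %d parameters\n",
    if (object@trained) "trained" else "untrained",
    cfg@inputResolution, cfg@inputResolution, cfg@numChannels,
    cfg@numFilters, cfg@kernelSize, cfg@kernelSize, np))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d TN=%d (positive = normal)\n",
              object@tp, object@fp, object@fn, object@tn))
})
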