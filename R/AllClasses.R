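.LABELS <- c("normal", "pathological", "unknown")
.MASKS <- c("untouched", "interpolated", "removed-adjacent")

#' FHRRecord: a raw fetal heart-rate trace
#'
#' Container for a single cardiotocographic fetal heart-rate (FHR) recording
#' sampled at a fixed rate (4 Hz in the supported databases), together with
#' the umbilical-artery pH measured after delivery, the binary class label
#' derived from it, and any further clinical metadata. Raw traces may contain
#' zero-valued samples (signal loss) and non-physiological values; those are
#' handled by [preprocessRecord()].
#'
#' @slot recordId character identifier of the recording.
#' @slot samples numeric vector of heart-rate values in beats per minute.
#' @slot fs sampling rate in Hz (4 for the supported databases).
#' @slot ph umbilical-artery pH, `NA` when not available.
#' @slot label one of `"normal"`, `"pathological"`, `"unknown"`.
#' @slot metadata named list of further clinical metadata.
#' @seealso [readRecord()], [labelFromPh()], [simulateRecord()]
#' @export
setClass("FHRRecord",
  slots = c(recordId = "character", samples = "numeric", fs = "numeric",
            ph = "numeric", label = "character", metadata = "list"),
  prototype = list(recordId = NA_character_, samples = numeric(), fs = 4,
                   ph = NA_real_, label = "unknown", metadata = list()),
  validity = function(object) {
    if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
      return("fs must be a single positive number")
    if (!object@label %in% .LABELS)
      return(sprintf("label must be one of %s", paste(.LABELS, collapse = ", ")))
    if (anyNA(object@samples))
      return("samples must not contain NA")
    TRUE
  })

#' Construct an FHRRecord
#'
#' When no explicit `label` is given it is derived from `ph` via
#' [labelFromPh()]; a record without pH and without an explicit label is
#' `"unknown"`. A sampling rate other than 4 Hz is accepted but reported,
#' since the cleaning rules are stated in seconds at 4 Hz.
#'
#' @param recordId character identifier.
#' @param samples numeric vector of heart-rate values (bpm).
#' @param fs sampling rate in Hz.
#' @param ph umbilical-artery pH or `NA`.
#' @param label explicit class label, or `NULL` to derive it from `ph`.
#' @param metadata named list of clinical metadata.
#' @return An [FHRRecord-class] object.
#' @examples
#' rec <- FHRRecord("demo", rep(140, 4800), ph = 7.20)
#' recordLabel(rec)
#' @export
FHRRecord <- function(recordId, samples, fs = 4, ph = NA_real_,
                      label = NULL, metadata = list()) {
  if (is.null(label)) {
    label <- if (is.na(ph)) "unknown" else labelFromPh(ph)
  }
  if (fs != 4) .msg("record %s uses fs = %g Hz (cleaning rules assume 4 Hz)",
                    recordId, fs)
  new("FHRRecord", recordId = as.character(recordId),
      samples = as.numeric(samples), fs = as.numeric(fs),
      ph = as.numeric(ph), label = label, metadata = metadata)
}

#' CleanSignal: a preprocessed, gap-free heart-rate trace
#'
#' Output of the artifact-removal pipeline: a trace with no zero samples and
#' every value inside the physiological band, plus a per-sample edit mask
#' recording which samples were interpolated or border a removed long gap.
#'
#' @slot sourceId identifier of the originating record.
#' @slot samples cleaned heart-rate values (bpm).
#' @slot fs sampling rate (Hz).
#' @slot editMask per-sample flag, one of `"untouched"`, `"interpolated"`,
#'   `"removed-adjacent"`.
#' @slot label class label inherited from the source record.
#' @slot range physiological band enforced on the samples (bpm).
#' @seealso [preprocessRecord()], [replaceExtremes()]
#' @export
setClass("CleanSignal",
  slots = c(sourceId = "character", samples = "numeric", fs = "numeric",
            editMask = "character", label = "character", range = "numeric"),
  prototype = list(fs = 4, label = "unknown", range = c(50, 200)),
  validity = function(object) {
    if (length(object@editMask) != length(object@samples))
      return("editMask length must equal samples length")
    if (!all(object@editMask %in% .MASKS))
      return("invalid editMask values")
    if (any(object@samples == 0))
      return("clean signal must not contain zero samples")
    if (any(object@samples < object@range[1] | object@samples > object@range[2]))
      return("clean signal must lie within the physiological range")
    TRUE
  })

#' Scalogram: continuous wavelet transform coefficients
#'
#' Matrix of CWT coefficients of a cleaned trace; rows are scales, columns
#' translations (one per signal sample).
#'
#' @slot coeffs numeric matrix, `length(scales)` rows and one column per
#'   signal sample.
#' @slot scales integer scale vector (in sample units).
#' @slot dt seconds per sample of the analysed signal.
#' @slot family mother wavelet family (`"db2"` or `"sym2"`).
#' @slot exponent dyadic scale exponent J; scales run 1..2^J.
#' @slot sourceId identifier of the analysed record.
#' @seealso [cwtCoefficients()], [renderImage()]
#' @export
setClass("Scalogram",
  slots = c(coeffs = "matrix", scales = "numeric", dt = "numeric",
            family = "character", exponent = "numeric", sourceId = "character"),
  validity = function(object) {
    if (nrow(object@coeffs) != length(object@scales))
      return("coeffs must have one row per scale")
    TRUE
  })

#' TFImage: a rendered time-frequency image
#'
#' A square RGB rendering of a scalogram with intensities in `[0, 1]`,
#' carrying the class label of the source record.
#'
#' @slot pixels numeric array of shape (R, R, 3) with values in `[0, 1]`.
#' @slot label class label.
#' @slot sourceId identifier of the source record.
#' @slot family mother wavelet family used.
#' @slot exponent dyadic scale exponent used.
#' @seealso [renderImage()]
#' @export
setClass("TFImage",
  slots = c(pixels = "array", label = "character", sourceId = "character",
            family = "character", exponent = "numeric"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[1] != d[2] || d[3] != 3)
      return("pixels must be a square (R, R, 3) array")
    if (min(object@pixels) < 0 || max(object@pixels) > 1)
      return("pixel intensities must lie in [0, 1]")
    TRUE
  })

#' TFImageSet: a labelled collection of time-frequency images
#'
#' Images are stored as a single (R, R, 3, N) array for efficient batch
#' processing; `meta` keeps one row per image (source record, wavelet family,
#' scale exponent).
#'
#' @slot images numeric array (R, R, 3, N), intensities in `[0, 1]`.
#' @slot labels character vector of length N.
#' @slot meta data.frame with columns `sourceId`, `family`, `exponent`.
#' @seealso [buildImageDataset()], [makeBenchmarkSet()]
#' @export
setClass("TFImageSet",
  slots = c(images = "array", labels = "character", meta = "data.frame"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 4 || d[3] != 3)
      return("images must be an (R, R, 3, N) array")
    if (d[4] != length(object@labels) || d[4] != nrow(object@meta))
      return("labels and meta must have one entry per image")
    TRUE
  })

#' CNNConfig: architecture and training hyperparameters
#'
#' Defaults are the optimum configuration of the pipeline: 5x5 kernels, 15
#' filters, 20 epochs, mini-batch 50, on 64x64x3 input images; SGD with
#' momentum 0.9, initial learning rate 0.01 dropped by a factor 0.1 every 10
#' epochs, L2 regularisation 1e-4, dropout 0.5 and cross-channel (local
#' response) normalisation with alpha 1e-3, beta 0.75, K 2 over a 5-channel
#' window. See [cnnConfig()].
#'
#' @slot inputResolution input image side length in pixels.
#' @slot numChannels input channels (3 for RGB scalograms).
#' @slot kernelSize convolution kernel side length.
#' @slot numFilters number of convolution filters.
#' @slot maxEpochs training epochs.
#' @slot miniBatch mini-batch size.
#' @slot poolSize,poolStride max-pooling geometry.
#' @slot dropoutP dropout probability after the hidden FC layer.
#' @slot lrnAlpha,lrnBeta,lrnK,lrnWindow cross-channel normalisation
#'   parameters.
#' @slot momentum SGD momentum.
#' @slot initialLr initial learning rate.
#' @slot lrDropFactor,lrDropPeriod learning-rate schedule (multiplicative
#'   drop every `lrDropPeriod` epochs).
#' @slot l2Factor L2 regularisation factor.
#' @slot fcWidth width of the hidden fully-connected layer.
#' @slot initScheme weight initialisation scheme, `"he"` (fan-in scaled,
#'   default) or `"gaussian"` (fixed `initStd`).
#' @slot initStd standard deviation used by the `"gaussian"` scheme.
#' @slot cropPad reflect-padding width for random-crop augmentation.
#' @slot seed RNG seed for initialisation, shuffling, cropping and dropout.
#' @export
setClass("CNNConfig",
  slots = c(inputResolution = "numeric", numChannels = "numeric",
            kernelSize = "numeric", numFilters = "numeric",
            maxEpochs = "numeric", miniBatch = "numeric",
            poolSize = "numeric", poolStride = "numeric",
            dropoutP = "numeric", lrnAlpha = "numeric", lrnBeta = "numeric",
            lrnK = "numeric", lrnWindow = "numeric", momentum = "numeric",
            initialLr = "numeric", lrDropFactor = "numeric",
            lrDropPeriod = "numeric", l2Factor = "numeric",
            fcWidth = "numeric", initScheme = "character",
            initStd = "numeric", cropPad = "numeric",
            seed = "numeric"),
  validity = function(object) {
    convOut <- object@inputResolution - object@kernelSize + 1
    if (convOut <= 0)
      return("kernel larger than input image")
    if (convOut %% object@poolSize != 0)
      return(sprintf(
        "post-convolution width %d is not divisible by the pool size %d",
        convOut, object@poolSize))
    if (object@dropoutP < 0 || object@dropoutP >= 1)
      return("dropoutP must lie in [0, 1)")
    if (object@lrnK <= 0) return("lrnK must be positive")
    if (any(c(object@numFilters, object@maxEpochs, object@miniBatch,
              object@fcWidth) < 1))
      return("counts must be positive")
    TRUE
  })

#' CNNModel: the eight-layer convolutional classifier
#'
#' Layer stack: image input (random-crop augmentation, zero-centering) ->
#' convolution -> ReLU -> cross-channel normalisation -> 2x2 max pooling ->
#' fully-connected -> dropout -> softmax classification. Class order of the
#' output is `("normal", "pathological")`; the normal class is the positive
#' class throughout the package.
#'
#' @slot config the [CNNConfig-class] used to build the model.
#' @slot params named list of weights and biases (`Wc`, `bc`, `W1`, `b1`,
#'   `W2`, `b2`).
#' @slot meanImage training-set mean image used for zero-centering (or
#'   `NULL` before training).
#' @slot history data.frame of per-iteration training loss and accuracy.
#' @slot trained logical.
#' @seealso [buildModel()], [trainModel()]
#' @export
setClass("CNNModel",
  slots = c(config = "CNNConfig", params = "list", meanImage = "ANY",
            history = "data.frame", trained = "logical"),
  prototype = list(meanImage = NULL, history = data.frame(),
                   trained = FALSE))

#' ConfusionCounts: binary confusion-matrix counts
#'
#' The normal fetal state is the positive class: `tp` counts
#' normal-predicted-normal, `tn` pathological-predicted-pathological.
#'
#' @slot tp,fp,fn,tn nonnegative integer counts.
#' @seealso [confusionCounts()], [classificationMetrics()]
#' @export
setClass("ConfusionCounts",
  slots = c(tp = "integer", fp = "integer", fn = "integer", tn = "integer"),
  validity = function(object) {
    if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
      return("counts must be nonnegative")
    TRUE
  })
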